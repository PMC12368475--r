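#' Canonical behavior labels
#'
#' The ethogram used throughout the package is a closed set of three oral
#' food processing behaviors: anterior ingestion (bites on the incisors and
#' canines), posterior ingestion (bites on the premolars and molars), and
#' chewing.  Tongue-palatal processing and limb pulls are outside this
#' ethogram and are rejected on input.
#'
#' @return Character vector of the three canonical labels, in display order.
#' @export
#' @examples
#' behavior_labels()
behavior_labels <- function() {
  c("ANTERIOR_INGESTION", "POSTERIOR_INGESTION", "CHEW")
}

# Input aliases accepted by the readers; canonical labels are always used
# on output.  Keys are lower-cased and stripped of spaces/dots before lookup.
.label_aliases <- c(
  "anterior_ingestion"  = "ANTERIOR_INGESTION",
  "anteriorbite"        = "ANTERIOR_INGESTION",
  "anterioringestion"   = "ANTERIOR_INGESTION",
  "antbite"             = "ANTERIOR_INGESTION",
  "ab"                  = "ANTERIOR_INGESTION",
  "posterior_ingestion" = "POSTERIOR_INGESTION",
  "posteriorbite"       = "POSTERIOR_INGESTION",
  "posterioringestion"  = "POSTERIOR_INGESTION",
  "postbite"            = "POSTERIOR_INGESTION",
  "pb"                  = "POSTERIOR_INGESTION",
  "chew"                = "CHEW",
  "chewing"             = "CHEW",
  "c"                   = "CHEW"
)

#' Canonicalize behavior labels
#'
#' Maps common shorthand ("ant. bite", "post_bite", "AB", "chew", ...) onto
#' the canonical closed label set.  Unknown labels yield `NA`, which the
#' readers turn into a parse error naming the offending row.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels (`NA` where unrecognized).
#' @export
#' @examples
#' canonical_label(c("ant. bite", "Chew", "post_bite"))
canonical_label <- function(x) {
  key <- gsub("[ ._-]", "", tolower(trimws(as.character(x))))
  out <- unname(.label_aliases[key])
  out
}
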