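#' @keywords internal
"_PACKAGE"

# The nine relation labels of the 2010 i2b2/VA relation task. "None" marks a
# candidate pair with no annotated relation.
RELATION_LABELS <- c("TeCP", "TeRP", "PIP", "TrCP", "TrAP", "TrWP", "TrNAP",
                     "TrIP", "None")

ENTITY_TYPES <- c("problem", "treatment", "test")

#' Relation labels of the clinical relation task
#'
#' Returns the nine class labels used throughout the package: the eight i2b2
#' 2010 relation types between problems, treatments and tests, plus `"None"`
#' for unrelated candidate pairs.
#'
#' @return Character vector of length 9.
#' @export
relation_labels <- function() RELATION_LABELS

assert_label <- function(x, what = "label") {
  bad <- setdiff(unique(x), RELATION_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded uniform matrix, used by all random initializers
runif_mat <- function(nr, nc, a) {
  matrix(stats::runif(nr * nc, -a, a), nrow = nr, ncol = nc)
}
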