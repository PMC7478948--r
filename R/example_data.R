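#' Worked-example Fazekas confusion matrices
#'
#' Confusion matrices of visually rated versus volume-derived Fazekas
#' groups for a 147-subject CT-MRI cohort (50 / 48 / 49 subjects in groups
#' 0-1 / 2 / 3), used as worked examples in the documentation and tests:
#' both matrices give a share of correct estimates of 0.78.
#'
#' @return A list with 3x3 integer matrices `ct` and `flair` (rows: visual
#'   score, columns: automatic score; levels 0-1, 2, 3).
#' @examples
#' cms <- example_fazekas_confusion()
#' confusion_accuracy(cms$ct)
#' @export
example_fazekas_confusion <- function() {
  lev <- c("0_1", "2", "3")
  ct <- matrix(c(43, 7, 0,
                 12, 28, 8,
                 0, 5, 44), nrow = 3, byrow = TRUE,
               dimnames = list(visual = lev, automatic = lev))
  flair <- matrix(c(37, 13, 0,
                    7, 37, 4,
                    0, 9, 40), nrow = 3, byrow = TRUE,
                  dimnames = list(visual = lev, automatic = lev))
  list(ct = ct, flair = flair)
}
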