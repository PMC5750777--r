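#' Published benchmark scores on the Herlev dataset
#'
#' Precision, recall, F1 and Cohen's kappa previously reported for the
#' All-Features, P-Fuzzy (standard-PSO wrapper) and Q-Fuzzy (quantum-
#' behaved wrapper) approaches on the 917-cell Herlev benchmark: overall
#' scores for neighbour counts k = 2..7 (`scenario == "by_k"`) and
#' per-class scores at each approach's best k (`scenario == "by_class"`).
#' These figures serve as a worked-example input for the F1 consistency
#' check (`f1 == 2 P R / (P + R)` up to printed rounding); the package does
#' not reproduce them computationally, since the underlying dataset is an
#' external download.
#'
#' @return Data frame with columns `scenario`, `approach`, `k`, `category`,
#'   `precision`, `recall`, `f1`, `kappa` (kappa only for overall rows).
#' @examples
#' ref <- reference_scores()
#' head(ref)
#' max(abs(f1_score(ref$precision, ref$recall) - ref$f1))
#' @export
reference_scores <- function() {
  utils::read.csv(
    system.file("extdata", "herlev_reference_scores.csv", package = "qfuzzy"),
    stringsAsFactors = FALSE
  )
}
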