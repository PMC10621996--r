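#' Synthetic stand-in screen score table
#'
#' The per-gene score tables of the published spatacsin-interactor siRNA
#' screen are not redistributed with this package; only the three
#' positive-control (Spg11 siRNA) scores and the pass counts of the two
#' readouts are public. This generator builds a *synthetic* stand-in
#' table of per-condition scores whose pass/fail structure against the
#' positive-control gates (classifier gate 0.21, tubulation gate 0.55,
#' minimal-effect rule) reproduces the published structure: 28
#' conditions pass the classifier readout, 11 pass the tubulation
#' readout, and 8 pass both. Individual score values are random draws
#' within the pass or fail range and carry no biological meaning.
#'
#' @param n_conditions Total number of candidate conditions (default
#'   40).
#' @param n_nn_pass,n_tub_pass,n_common Programmed pass counts for the
#'   classifier readout, the tubulation readout, and their overlap.
#' @param nn_gate,tub_gate Gate values the structure is built against.
#' @param seed RNG seed.
#' @return Tibble: `condition_id`, `mean_ko_probability`,
#'   `tubulation_index`.
#' @export
synthetic_screen_scores <- function(n_conditions = 40, n_nn_pass = 28,
                                    n_tub_pass = 11, n_common = 8,
                                    nn_gate = 0.21, tub_gate = 0.55,
                                    seed = 1) {
  stopifnot(n_common <= n_nn_pass, n_common <= n_tub_pass,
            n_nn_pass + n_tub_pass - n_common <= n_conditions)
  with_seed(seed, {
    id <- sprintf("cond%02d", seq_len(n_conditions))
    nn_pass <- seq_len(n_nn_pass)
    tub_pass <- c(seq_len(n_common),
                  n_nn_pass + seq_len(n_tub_pass - n_common))
    prob <- runif(n_conditions, 0.02, nn_gate - 0.03)
    prob[nn_pass] <- runif(n_nn_pass, nn_gate + 0.02, 0.95)
    idx <- runif(n_conditions, tub_gate + 0.05, 0.98)
    idx[tub_pass] <- runif(n_tub_pass, 0.02, tub_gate - 0.05)
    tibble(condition_id = id, mean_ko_probability = prob,
           tubulation_index = idx)
  })
}
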