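#' Measure parameters
#'
#' Bundles every tunable parameter of the similarity measure in one place so
#' that spheres, calibration tables and alignments built under one
#' parameterization are never silently mixed with another (see
#' [params_fingerprint()]).
#'
#' @param radius Sphere radius in Angstrom. A residue belongs to the aa-sphere
#'   of a centre residue when any of its heavy atoms lies within `radius` of
#'   the centre's alpha-carbon. Default 9.
#' @param d_s Scale parameter (Angstrom) of the distance score
#'   `1 / (1 + (d / d_s)^2)` used inside the sphere similarity. Default 2.
#' @param gap_penalty Additive penalty per gap position in the global
#'   log-score alignment. Must be negative; default `log(0.75)`.
#' @param d0_min Lower clamp (Angstrom) for the TM-score scale
#'   `d0(L) = 1.24 (L - 15)^{1/3} - 1.8`. Default 0.5.
#' @param sm_floor Floor applied to SM-scores before taking logarithms, so the
#'   dynamic programming matrix stays finite. Default 1e-8.
#' @param max_tm_iterations Maximum rounds of alignment/superposition
#'   improvement in [tm_optimize()]. Default 20.
#' @param tol Convergence tolerance on the TM-score during [tm_optimize()].
#'   Default 1e-6.
#'
#' @return An object of class `"sprot_params"`.
#' @export
#' @examples
#' p <- sprot_params()
#' p$radius
sprot_params <- function(radius = 9, d_s = 2, gap_penalty = log(0.75),
                         d0_min = 0.5, sm_floor = 1e-8,
                         max_tm_iterations = 20L, tol = 1e-6) {
  stopifnot(radius > 0, d_s > 0, gap_penalty < 0, d0_min > 0,
            sm_floor > 0, max_tm_iterations >= 1, tol > 0)
  structure(list(radius = radius, d_s = d_s, gap_penalty = gap_penalty,
                 d0_min = d0_min, sm_floor = sm_floor,
                 max_tm_iterations = as.integer(max_tm_iterations),
                 tol = tol),
            class = "sprot_params")
}

#' @export
print.sprot_params <- function(x, ...) {
  cat("SProt measure parameters\n")
  cat(sprintf("  sphere radius : %.3g A\n", x$radius))
  cat(sprintf("  d_s           : %.3g A\n", x$d_s))
  cat(sprintf("  gap penalty   : %.6g (= log %.4g)\n",
              x$gap_penalty, exp(x$gap_penalty)))
  cat(sprintf("  d0 clamp      : %.3g A\n", x$d0_min))
  invisible(x)
}

#' Parameter fingerprint
#'
#' A short string identifying the parameters a calibration table or search
#' index was built under. Artifacts refuse to combine when fingerprints
#' disagree.
#'
#' @param params A [sprot_params()] object.
#' @return A single string.
#' @export
params_fingerprint <- function(params) {
  stopifnot(inherits(params, "sprot_params"))
  paste0("radius=", format(params$radius, digits = 10),
         ";d_s=", format(params$d_s, digits = 10),
         ";gap=", format(params$gap_penalty, digits = 10),
         ";d0_min=", format(params$d0_min, digits = 10))
}

# TM-score length scale, clamped from below.
tm_d0 <- function(L_T, d0_min = 0.5) {
  d0 <- 1.24 * sign(L_T - 15) * abs(L_T - 15)^(1 / 3) - 1.8
  max(d0, d0_min)
}
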