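#' Ground-truth RSF coefficients
#'
#' The four selection coefficients of the exponential resource selection
#' function used to simulate telemetry: canopy cover (`beta_cc`), snow
#' depth (`beta_sd`, per cm, negative: snow avoidance), feeding-site
#' proximity (`beta_prox`, m, positive: attraction to sites) and the
#' snow-by-proximity interaction (`beta_inter`, m per cm, non-negative:
#' sites more attractive under deep snow).
#'
#' @param beta_cc,beta_sd,beta_prox,beta_inter numeric coefficients.
#' @param validate enforce the default-fixture sign constraints; disable
#'   only for null or counterfactual simulations.
#' @return a `truth_rsf` object.
#' @export
truth_rsf <- function(beta_cc = 0.8, beta_sd = -0.05, beta_prox = 300,
                      beta_inter = 5, validate = TRUE) {
  if (validate) {
    if (beta_sd >= 0) stop("beta_sd must be negative (snow avoidance)")
    if (beta_prox <= 0) stop("beta_prox must be positive (site attraction)")
    if (beta_inter < 0) stop("beta_inter must be non-negative")
    if (beta_cc <= 0) stop("beta_cc must be positive (canopy selection)")
  }
  structure(list(beta_cc = beta_cc, beta_sd = beta_sd,
                 beta_prox = beta_prox, beta_inter = beta_inter),
            class = "truth_rsf")
}

# linear predictor of the exponential RSF over covariate vectors/matrices
rsf_linear_predictor <- function(beta, cc, sd, prox) {
  beta[["beta_cc"]] * cc + beta[["beta_sd"]] * sd +
    beta[["beta_prox"]] * prox + beta[["beta_inter"]] * sd * prox
}

#' Simulate telemetry relocations from a known RSF
#'
#' For each animal-day, one cell of the home-range mask is drawn from the
#' discrete distribution with weight `exp(linear predictor)` under that
#' month's covariates, and the fix is placed uniformly within the cell.
#' Daily draws are independent: the analysis subsamples telemetry to one
#' fix per animal-day precisely to break autocorrelation, so a point
#' process is the appropriate generator. With `fixes_per_day > 1`,
#' additional same-day fixes are emitted (mirroring high-frequency GPS
#' schedules) so downstream subsampling is exercised.
#'
#' @param truth a [truth_rsf()].
#' @param covariates named list keyed `"<winter>_<month>"`, each element a
#'   list with aligned `grid_raster`s `cc`, `sd`, `prox`.
#' @param home_mask `grid_raster` 0/1 mask of available cells.
#' @param n_animals number of animals.
#' @param days_per_month telemetry days per winter-month.
#' @param seed integer RNG seed.
#' @param fixes_per_day fixes per animal-day (default 1).
#' @param period period tag copied to every row.
#' @param animal_prefix prefix for animal ids.
#' @return data.frame: `animal_id`, `date`, `month`, `winter`, `x`, `y`,
#'   `period`.
#' @export
simulate_relocations <- function(truth, covariates, home_mask, n_animals = 20,
                                 days_per_month = 30, seed = 1,
                                 fixes_per_day = 1, period = "sim",
                                 animal_prefix = "A") {
  cells <- which(home_mask$values == 1)
  if (length(cells) == 0L) stop("home mask is empty")
  cs <- home_mask$cell_size
  rows <- ((cells - 1L) %% nrow(home_mask$values)) + 1L
  cols <- ((cells - 1L) %/% nrow(home_mask$values)) + 1L
  cx <- home_mask$x_origin + (cols - 0.5) * cs
  cy <- home_mask$y_origin + (rows - 0.5) * cs

  out <- vector("list", length(covariates))
  for (k in seq_along(covariates)) {
    key <- names(covariates)[k]
    cov <- covariates[[key]]
    stopifnot_aligned(home_mask, cov$cc, cov$sd, cov$prox)
    lp <- rsf_linear_predictor(truth, cov$cc$values[cells],
                               cov$sd$values[cells], cov$prox$values[cells])
    if (!any(is.finite(lp))) stop("all selection weights are non-finite")
    w <- exp(lp - max(lp, na.rm = TRUE))
    w[!is.finite(w)] <- 0
    if (sum(w) <= 0) stop("all selection weights are zero")

    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    winter <- parts[1]; month <- parts[2]
    set.seed(derive_seed(seed, paste("reloc", key)))
    n_draw <- n_animals * days_per_month * fixes_per_day
    pick <- sample.int(length(cells), n_draw, replace = TRUE, prob = w)
    out[[k]] <- data.frame(
      animal_id = rep(sprintf("%s%02d", animal_prefix, seq_len(n_animals)),
                      each = days_per_month * fixes_per_day),
      date = rep(rep(sprintf("%s-%s-%02d", winter, month, seq_len(days_per_month)),
                     each = fixes_per_day), times = n_animals),
      month = month, winter = winter,
      x = cx[pick] + stats::runif(n_draw, -0.5, 0.5) * cs,
      y = cy[pick] + stats::runif(n_draw, -0.5, 0.5) * cs,
      period = period
    )
  }
  do.call(rbind, out)
}
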