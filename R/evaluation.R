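#' Kling-Gupta efficiency with decomposition
#'
#' `KGE = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2)` where `r` is
#' the linear correlation between simulation and observation,
#' `alpha = sd(sim)/sd(obs)` the variability ratio, and
#' `beta = mean(sim)/mean(obs)` the bias ratio. KGE ranges from `-Inf` to 1
#' (perfect agreement). A simulation with zero variance is assigned
#' `r = 0` by convention; under that convention a constant prediction equal
#' to the observed mean scores `1 - sqrt(2)` (about -0.41), the
#' mean-benchmark reference against which model skill is judged.
#' Standard deviations are the sample (n-1) form.
#'
#' @param sim simulated series.
#' @param obs observed series (same length; pairs with non-finite entries
#'   are dropped).
#' @return an object of class `kge_result`: list with `kge`, `r`, `alpha`,
#'   `beta`, `n`.
#' @export
#' @examples
#' kge(c(2, 3, 4), c(1, 2, 3))$kge # 0.5
kge <- function(sim, obs) {
  if (length(sim) != length(obs)) stop_arg("sim and obs must match in length")
  ok <- is.finite(sim) & is.finite(obs)
  sim <- sim[ok]; obs <- obs[ok]
  if (length(obs) < 2L) stop_arg("need at least 2 paired finite points")
  mu_o <- mean(obs); sd_o <- sd(obs)
  if (sd_o == 0) stop_arg("observations have zero variance")
  if (mu_o == 0) stop_arg("observations have zero mean")
  mu_s <- mean(sim); sd_s <- sd(sim)
  r <- if (sd_s == 0) 0 else cor(sim, obs)
  alpha <- sd_s / sd_o
  beta <- mu_s / mu_o
  structure(list(
    kge = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2),
    r = r, alpha = alpha, beta = beta, n = length(obs)),
    class = "kge_result")
}

#' @export
print.kge_result <- function(x, ...) {
  cat(sprintf("KGE %.4f (r %.4f, alpha %.4f, beta %.4f, n %d)\n",
              x$kge, x$r, x$alpha, x$beta, x$n))
  invisible(x)
}

#' Root mean square error
#' @param sim,obs paired series (>= 2 finite pairs).
#' @return RMSE (>= 0).
#' @export
#' @examples
#' rmse(c(1, 3), c(0, 2)) # 1
rmse <- function(sim, obs) {
  if (length(sim) != length(obs)) stop_arg("sim and obs must match in length")
  ok <- is.finite(sim) & is.finite(obs)
  if (sum(ok) < 2L) stop_arg("need at least 2 paired finite points")
  sqrt(mean((sim[ok] - obs[ok])^2))
}

#' Linear correlation between simulation and observation
#' @param sim,obs paired series (>= 2 finite pairs, both with variance).
#' @return Pearson correlation in \[-1, 1\].
#' @export
correlation <- function(sim, obs) {
  if (length(sim) != length(obs)) stop_arg("sim and obs must match in length")
  ok <- is.finite(sim) & is.finite(obs)
  if (sum(ok) < 2L) stop_arg("need at least 2 paired finite points")
  cor(sim[ok], obs[ok])
}

#' Summarise per-site skill by vegetation class
#'
#' Mirrors distribution summaries of site-level KGE: per class, the median,
#' the interquartile range, and the fraction of sites beating the
#' mean-benchmark reference `1 - sqrt(2)` (about -0.41).
#'
#' @param metrics data frame with columns `site_id`, `class` and `kge`.
#' @param benchmark reference KGE (default `1 - sqrt(2)`).
#' @return a tibble with one row per class: `class`, `n`, `median`, `q25`,
#'   `q75`, `iqr`, `frac_above_benchmark`. Empty classes are omitted with a
#'   warning.
#' @export
summarize_by_class <- function(metrics, benchmark = 1 - sqrt(2)) {
  need <- c("site_id", "class", "kge")
  if (!all(need %in% names(metrics))) {
    stop_arg("metrics must have columns site_id, class, kge")
  }
  cls <- unique(metrics$class)
  rows <- lapply(cls, function(cl) {
    v <- metrics$kge[metrics$class == cl & is.finite(metrics$kge)]
    if (length(v) == 0L) {
      warning("class '", cl, "' has no finite KGE values; omitted")
      return(NULL)
    }
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(class = cl, n = length(v), median = q[2],
                   q25 = q[1], q75 = q[3], iqr = q[3] - q[1],
                   frac_above_benchmark = mean(v > benchmark))
  })
  do.call(rbind, rows)
}
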