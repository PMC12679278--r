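#' Genetic parameters from genotypic variance, heritability and mean
#'
#' Computes the standard selection-genetics summary used to compare
#' traits in multi-environment trials. The phenotypic variance is
#' derived self-consistently from the genotypic variance and the
#' broad-sense heritability, `s2_p = s2_g / h2`, and:
#' \deqn{GCV = 100\,\sigma_g/\bar y,\quad PCV = 100\,\sigma_p/\bar y,}
#' \deqn{GA = k\,h^2\,\sigma_p,\quad GA\% = 100\,GA/\bar y,}
#' with `k` the standardized selection intensity (2.06 at 5% selected
#' fraction, the conventional default).
#'
#' @param var_g genotypic variance (trait units squared), >= 0.
#' @param h2 broad-sense heritability, in (0, 1].
#' @param mean trait grand mean, nonzero.
#' @param k selection intensity (default 2.06).
#' @return List with `var_g`, `var_p`, `h2`, `gcv`, `pcv` (percent),
#'   `ga` (trait units), `ga_pct` (percent), `k`.
#' @examples
#' genetic_parameters(var_g = 16536.58, h2 = 0.58, mean = 1233.74)
#' @export
genetic_parameters <- function(var_g, h2, mean, k = 2.06) {
  if (var_g < 0) stop("var_g must be nonnegative", call. = FALSE)
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
  if (mean == 0) stop("mean must be nonzero", call. = FALSE)
  var_p <- var_g / h2
  sd_p <- sqrt(var_p)
  ga <- k * h2 * sd_p
  list(var_g = var_g, var_p = var_p, h2 = h2,
       gcv = 100 * sqrt(var_g) / mean,
       pcv = 100 * sd_p / mean,
       ga = ga, ga_pct = 100 * ga / mean, k = k)
}

#' Descriptive statistics over genotype means
#'
#' @param x numeric vector (or matrix) of genotype means.
#' @return Named numeric vector `(mean, min, max)`.
#' @export
descriptive_stats <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || anyNA(x)) stop("nonempty finite input required",
                                       call. = FALSE)
  c(mean = mean(x), min = min(x), max = max(x))
}
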