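#' Two-way ANOVA for a balanced multi-environment trial
#'
#' Partitions the total sum of squares of a balanced genotype x
#' environment x replicate layout into Environment, Genotype,
#' Environment x Genotype and Error by the definitional sums:
#' \deqn{SS_E = gr\sum_j(\bar y_{.j.}-\bar y_{...})^2,\quad
#'       SS_G = er\sum_i(\bar y_{i..}-\bar y_{...})^2,}
#' \deqn{SS_{GE} = r\sum_{ij}(\bar y_{ij.}-\bar y_{i..}-\bar y_{.j.}
#'       +\bar y_{...})^2,\quad
#'       SS_{err} = \sum_{ijr}(y_{ijr}-\bar y_{ij.})^2.}
#' The additivity identity (their sum equals the total SS) is verified
#' internally. With a single replicate the error stratum has zero
#' degrees of freedom and is omitted.
#'
#' @param dataset a balanced [met_dataset].
#' @param trait trait to analyze.
#' @return A data frame of class `met_anova` with columns `source`, `df`,
#'   `ss`, `ms` and attributes `g`, `e`, `r`, `grand_mean`, `trait`.
#' @export
met_anova <- function(dataset, trait) {
  stopifnot(inherits(dataset, "met_dataset"))
  if (!trait %in% attr(dataset, "trait_names")) {
    stop("trait '", trait, "' not in dataset", call. = FALSE)
  }
  bal <- validate_balance(dataset)
  if (!bal$complete) {
    stop("unbalanced dataset: ", nrow(bal$offending_cells),
         " offending cell(s); ANOVA requires balance", call. = FALSE)
  }
  r <- bal$r
  dims <- met_dims(dataset)
  g <- dims$g; e <- dims$e
  y <- dataset[[trait]]
  gf <- factor(dataset$genotype, levels = attr(dataset, "genotype_order"))
  ef <- factor(dataset$environment, levels = attr(dataset, "environment_order"))
  grand <- mean(y)
  gm <- tapply(y, gf, mean)
  em <- tapply(y, ef, mean)
  cm <- tapply(y, list(gf, ef), mean)
  ss_e <- g * r * sum((em - grand)^2)
  ss_g <- e * r * sum((gm - grand)^2)
  ss_ge <- r * sum((sweep(sweep(cm, 1, gm), 2, em) + grand)^2)
  ss_err <- sum((y - cm[cbind(gf, ef)])^2)
  ss_tot <- sum((y - grand)^2)
  resid <- abs(ss_e + ss_g + ss_ge + ss_err - ss_tot)
  if (resid > 1e-8 * max(ss_tot, 1)) {
    stop("internal error: SS decomposition does not add up", call. = FALSE)
  }
  tab <- data.frame(
    source = c("Environment", "Genotype", "Environment:Genotype", "Error"),
    df = c(e - 1, g - 1, (g - 1) * (e - 1), g * e * (r - 1)),
    ss = c(ss_e, ss_g, ss_ge, ss_err),
    stringsAsFactors = FALSE
  )
  if (r == 1) tab <- tab[tab$source != "Error", ]
  tab$ms <- tab$ss / tab$df
  structure(tab, g = g, e = e, r = r, grand_mean = grand, trait = trait,
            class = c("met_anova", "data.frame"))
}

#' Percent contribution of variance sources
#'
#' Expresses each non-error source (Environment, Genotype,
#' Environment x Genotype) as a percentage of the summed source mean
#' squares, `100 * MS_s / (MS_E + MS_G + MS_GE)`. The mean-square share
#' is the committed default convention; the more conventional
#' sum-of-squares share is available via `method = "ss"`.
#'
#' @param x a [met_anova] table, or a numeric length-3 vector of mean
#'   squares ordered (Environment, Genotype, Environment x Genotype).
#' @param method `"ms"` (default) or `"ss"`.
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' percent_contribution(c(13223.81, 794.30, 2028.26))
#' @export
percent_contribution <- function(x, method = c("ms", "ss")) {
  method <- match.arg(method)
  sources <- c("Environment", "Genotype", "Environment:Genotype")
  if (inherits(x, "met_anova")) {
    idx <- match(sources, x$source)
    if (anyNA(idx)) stop("ANOVA table lacks a required source", call. = FALSE)
    val <- if (method == "ms") x$ms[idx] else x$ss[idx]
  } else {
    x <- as.numeric(x)
    if (length(x) != 3 || anyNA(x)) {
      stop("need the three source mean squares ",
           "(Environment, Genotype, Environment:Genotype)", call. = FALSE)
    }
    if (method == "ss") {
      stop("method = 'ss' needs a full met_anova table", call. = FALSE)
    }
    val <- x
  }
  stats::setNames(100 * val / sum(val), sources)
}

#' Method-of-moments variance components
#'
#' Under the balanced random two-way model the expected mean squares are
#' `E[MS_err] = s2_err`, `E[MS_GE] = s2_err + r*s2_ge`,
#' `E[MS_G] = s2_err + r*s2_ge + e*r*s2_g`, inverted here to
#' `s2_err = MS_err`, `s2_ge = (MS_GE - MS_err)/r`,
#' `s2_g = (MS_G - MS_GE)/(e*r)`. Negative estimates are truncated at
#' zero and flagged.
#'
#' @param anova a [met_anova] with an error stratum (r >= 2), or `NULL`
#'   if the mean squares are supplied directly.
#' @param ms_g,ms_ge,ms_err mean squares, read from `anova` when given.
#' @param e,r layout dimensions, read from `anova` when given.
#' @return List with `var_g`, `var_ge`, `var_err` and a logical
#'   `truncated` vector flagging zero-truncated components.
#' @export
variance_components <- function(anova = NULL, ms_g, ms_ge, ms_err, e, r) {
  if (!is.null(anova)) {
    stopifnot(inherits(anova, "met_anova"))
    if (!"Error" %in% anova$source) {
      stop("insufficient df: error stratum absent (r = 1)", call. = FALSE)
    }
    ms_g <- anova$ms[anova$source == "Genotype"]
    ms_ge <- anova$ms[anova$source == "Environment:Genotype"]
    ms_err <- anova$ms[anova$source == "Error"]
    e <- attr(anova, "e"); r <- attr(anova, "r")
  }
  if (r < 2) stop("insufficient df: need r >= 2", call. = FALSE)
  raw <- c(var_g = (ms_g - ms_ge) / (e * r),
           var_ge = (ms_ge - ms_err) / r,
           var_err = ms_err)
  truncated <- raw < 0
  if (any(truncated)) {
    warning("negative variance component estimate(s) truncated to 0: ",
            paste(names(raw)[truncated], collapse = ", "), call. = FALSE)
  }
  est <- pmax(raw, 0)
  list(var_g = est[["var_g"]], var_ge = est[["var_ge"]],
       var_err = est[["var_err"]], truncated = truncated)
}

#' ANOVA-based broad-sense heritability on a genotype-mean basis
#'
#' `h2 = s2_g / (s2_g + s2_ge/e + s2_err/(e*r))` — an alternative,
#' clearly labeled estimator; the genetic-parameter routines instead take
#' heritability as an input and derive the phenotypic variance from it.
#'
#' @param vc output of [variance_components()].
#' @param e,r layout dimensions.
#' @return Heritability in `[0, 1]`.
#' @export
heritability_anova <- function(vc, e, r) {
  denom <- vc$var_g + vc$var_ge / e + vc$var_err / (e * r)
  if (denom <= 0) return(NA_real_)
  vc$var_g / denom
}

#' Least significant difference yardstick
#'
#' Pairwise LSD for genotype means averaged over environments and
#' replicates: `t_{1-alpha/2, df_err} * sqrt(2 * MS_err / (r * e))`.
#' Reported as a descriptive yardstick.
#'
#' @param anova a [met_anova] with an error stratum.
#' @param alpha significance level (default 0.05).
#' @return The LSD value in trait units.
#' @export
lsd_threshold <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "met_anova"))
  if (!"Error" %in% anova$source) {
    stop("error stratum absent (r = 1)", call. = FALSE)
  }
  ms_err <- anova$ms[anova$source == "Error"]
  df_err <- anova$df[anova$source == "Error"]
  e <- attr(anova, "e"); r <- attr(anova, "r")
  stats::qt(1 - alpha / 2, df_err) * sqrt(2 * ms_err / (r * e))
}
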