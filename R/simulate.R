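#' Configure a balanced MET simulation
#'
#' Defines the generative model for a balanced genotype x environment x
#' replicate trial with additive effects:
#' \deqn{Y_{ijr} = \mu + G_i + E_j + GE_{ij} + \varepsilon_{ijr}}
#' with \eqn{G_i \sim N(0, \sigma^2_g)}, \eqn{E_j \sim N(0, \sigma^2_e)},
#' \eqn{GE_{ij} \sim N(0, \sigma^2_{ge})} and
#' \eqn{\varepsilon \sim N(0, \sigma^2_\epsilon)}, all mutually
#' independent. When `crossover` is supplied, the interaction is instead
#' built as a rank-1 product of genotype loadings and group-signed
#' environment loadings, rescaled to the requested interaction variance,
#' so that genotype rankings flip between environment groups and the 2-D
#' GGE representation of the interaction is exact by construction.
#'
#' Default dimensions and variances describe a 64-genotype, 4-location,
#' 2-replicate seed-yield trial (kg/ha scale).
#'
#' @param g,e,r genotypes, environments, replicates per cell.
#' @param mu grand mean (trait units).
#' @param var_g,var_e,var_ge,var_err nonnegative variance components
#'   (trait units squared).
#' @param crossover optional [crossover_spec()].
#' @param sum_to_zero if `TRUE`, drawn effect vectors are centered to sum
#'   to zero exactly (useful for exact small-sample checks); default
#'   `FALSE`, leaving sampling deviation for estimators to absorb.
#' @param seed integer seed; a fixed seed makes [simulate_met()] output
#'   bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(g = 64, e = 4, r = 2,
                       mu = 1233.74,
                       var_g = 16536.58, var_e = 271165,
                       var_ge = 95370.46, var_err = 27988,
                       crossover = NULL, sum_to_zero = FALSE, seed = 1L) {
  if (g < 2 || e < 2 || r < 1) {
    stop("invalid dimensions: need g >= 2, e >= 2, r >= 1", call. = FALSE)
  }
  vars <- c(var_g = var_g, var_e = var_e, var_ge = var_ge, var_err = var_err)
  if (any(vars < 0)) {
    stop("negative variance component: ",
         paste(names(vars)[vars < 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(crossover)) {
    stopifnot(inherits(crossover, "crossover_spec"))
    if (crossover$n_groups > e) {
      stop("crossover groups exceed environment count", call. = FALSE)
    }
  }
  structure(list(g = as.integer(g), e = as.integer(e), r = as.integer(r),
                 mu = mu, var_g = var_g, var_e = var_e, var_ge = var_ge,
                 var_err = var_err, crossover = crossover,
                 sum_to_zero = isTRUE(sum_to_zero), seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify planted crossover interaction
#'
#' Partitions the environments into `n_groups` contiguous groups with
#' alternating interaction sign; genotypes then rank oppositely between
#' adjacent groups, the textbook crossover-interaction pattern that the
#' which-won-where analysis must recover.
#'
#' @param n_groups number of environment groups (>= 1).
#' @param magnitude relative loading magnitude per group; recycled to
#'   `n_groups`. The full interaction block is rescaled afterwards, so
#'   only ratios matter.
#' @return A list of class `crossover_spec`.
#' @export
crossover_spec <- function(n_groups, magnitude = 1) {
  if (n_groups < 1) stop("need at least one group", call. = FALSE)
  structure(list(n_groups = as.integer(n_groups),
                 magnitude = rep_len(magnitude, n_groups)),
            class = "crossover_spec")
}

# internal: contiguous environment group index, length e
crossover_groups <- function(e, n_groups) {
  sort(rep_len(seq_len(n_groups), e))
}

#' Simulate a balanced multi-environment trial
#'
#' @param config a [sim_config()].
#' @return A [met_dataset] with one trait column `"sim"` and labels
#'   `G1..Gg`, `E1..Ee`, replicates `R1..Rr`.
#' @examples
#' d <- simulate_met(sim_config(g = 4, e = 3, r = 2, seed = 7))
#' validate_balance(d)
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$g; e <- config$e; r <- config$r
  set.seed(config$seed)
  draw <- function(n, v) {
    x <- stats::rnorm(n, 0, sqrt(v))
    if (config$sum_to_zero && n > 1) x <- x - mean(x)
    x
  }
  G <- draw(g, config$var_g)
  E <- draw(e, config$var_e)
  if (is.null(config$crossover)) {
    GE <- matrix(draw(g * e, config$var_ge), g, e)
  } else {
    grp <- crossover_groups(e, config$crossover$n_groups)
    sgn <- (-1)^(grp + 1)                       # alternating group sign
    d_j <- sgn * config$crossover$magnitude[grp]
    s_i <- stats::rnorm(g)
    GE <- outer(s_i, d_j)
    if (config$var_ge > 0) {
      GE <- GE * sqrt(config$var_ge / mean(GE^2))
    } else {
      GE[] <- 0
    }
  }
  cell <- config$mu + outer(G, E, "+") + GE     # g x e expected cell values
  records <- expand.grid(replicate = paste0("R", seq_len(r)),
                         environment = paste0("E", seq_len(e)),
                         genotype = paste0("G", seq_len(g)),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records <- records[, c("genotype", "environment", "replicate")]
  gi <- as.integer(sub("G", "", records$genotype))
  ej <- as.integer(sub("E", "", records$environment))
  records$sim <- cell[cbind(gi, ej)] +
    stats::rnorm(nrow(records), 0, sqrt(config$var_err))
  met_dataset(records, traits = "sim")
}

#' Planted mega-environment partition of a crossover simulation
#'
#' Returns the environment grouping the generator used, i.e. the
#' ground-truth mega-environment partition that [which_won_where()] must
#' recover on noise-free crossover data.
#'
#' @param config a [sim_config()] with a crossover specification.
#' @return A list of character vectors of environment labels, one per
#'   group.
#' @export
plant_crossover_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$crossover)) {
    stop("config has no crossover specification", call. = FALSE)
  }
  grp <- crossover_groups(config$e, config$crossover$n_groups)
  labs <- paste0("E", seq_len(config$e))
  unname(split(labs, grp))
}
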