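#' Specify a base linear phenotypic selection index
#'
#' The base index scores each genotype as a weighted sum of its trait
#' phenotypes, `I_i = sum_t w_t y_it`. Default weights are 1 per trait on
#' the raw scales (the classical base index). Weights are the caller's
#' economic judgement: traits where smaller is better (e.g. days to
#' maturity when earliness is desirable) should carry a negative weight.
#'
#' @param traits ordered character vector of trait names.
#' @param weights numeric economic weights, one per trait (recycled from
#'   length 1); at least one must be nonzero.
#' @param standardize if `TRUE`, traits are z-scored across genotypes
#'   before weighting.
#' @return A list of class `index_spec`.
#' @export
index_spec <- function(traits, weights = 1, standardize = FALSE) {
  if (length(traits) == 0) stop("need at least one trait", call. = FALSE)
  weights <- rep_len(as.numeric(weights), length(traits))
  if (all(weights == 0)) stop("at least one weight must be nonzero",
                              call. = FALSE)
  structure(list(traits = as.character(traits), weights = weights,
                 standardize = isTRUE(standardize)),
            class = "index_spec")
}

#' Compute the base linear phenotypic selection index
#'
#' @param trait_table genotype x trait data frame or matrix holding the
#'   spec's traits as columns; rownames (or a `genotype` column) label
#'   the genotypes.
#' @param spec an [index_spec()].
#' @return Named numeric vector of index values, one per genotype, in
#'   input row order.
#' @examples
#' tt <- data.frame(DTM = c(118, 115), BY = c(6.75, 7.23),
#'                  SY = c(1153.49, 1740.25),
#'                  row.names = c("G1", "G13"))
#' blpsi(tt, index_spec(c("DTM", "BY", "SY")))
#' @export
blpsi <- function(trait_table, spec) {
  stopifnot(inherits(spec, "index_spec"))
  tab <- as.data.frame(trait_table)
  labels <- if ("genotype" %in% names(tab)) {
    as.character(tab$genotype)
  } else {
    rownames(tab)
  }
  absent <- setdiff(spec$traits, names(tab))
  if (length(absent) > 0) {
    stop("spec trait(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  y <- as.matrix(tab[, spec$traits, drop = FALSE])
  if (any(!is.finite(y))) stop("missing trait values", call. = FALSE)
  if (spec$standardize) {
    sds <- apply(y, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance trait under standardize = TRUE: ",
           paste(spec$traits[sds == 0], collapse = ", "), call. = FALSE)
    }
    y <- scale(y)
  }
  stats::setNames(drop(y %*% spec$weights), labels)
}

#' Append the selection index to a MET dataset as a pseudo-trait
#'
#' The index is linear, so computing it per plot record and averaging
#' replicates later gives the same cell means as indexing the cell
#' means directly; the appended column therefore flows through
#' [to_two_way()] and the GGE engine unchanged.
#'
#' @param dataset a [met_dataset].
#' @param spec an [index_spec()] over raw trait scales
#'   (`standardize = TRUE` is rejected here because plot-level z-scoring
#'   would not commute with replicate averaging).
#' @param name name of the appended column (default `"BLPSI"`).
#' @return The dataset with the index column appended to its traits.
#' @export
add_selection_index <- function(dataset, spec, name = "BLPSI") {
  stopifnot(inherits(dataset, "met_dataset"), inherits(spec, "index_spec"))
  if (spec$standardize) {
    stop("standardized index cannot be appended per record; ",
         "compute it on a genotype-mean table instead", call. = FALSE)
  }
  df <- as.data.frame(dataset)
  df[[name]] <- blpsi(df, spec)
  met_dataset(df, traits = c(attr(dataset, "trait_names"), name))
}
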