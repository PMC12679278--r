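#' Environment-center a genotype-by-environment table
#'
#' Subtracts each environment's (column) mean, removing the grand mean
#' and environment main effects and leaving genotype main effect plus
#' genotype-by-environment interaction — the "GGE" part of the two-way
#' table. No column rescaling is applied (scaling = none).
#'
#' @param matrix a [trait_matrix] or plain numeric matrix (g >= 2 rows).
#' @return Numeric matrix of the same shape with every column mean 0.
#' @export
center_environment <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (nrow(m) < 2) stop("need at least 2 genotypes", call. = FALSE)
  sweep(m, 2, colMeans(m))
}

#' Fit a GGE model by singular value decomposition
#'
#' Decomposes the environment-centered table as
#' \eqn{\sum_n \lambda_n \gamma_{in} \delta_{jn}} and partitions the
#' singular values onto the scores. Genotype-focused partitioning
#' (`svp = "genotype"`, for genotype evaluation) assigns
#' genotype scores \eqn{U\Lambda} and environment scores \eqn{V};
#' environment-focused partitioning (`svp = "environment"`, for test
#' environment evaluation) assigns \eqn{U} and \eqn{V\Lambda}. In both
#' modes the full-rank score product reconstructs the centered table
#' exactly. Axis signs follow a fixed convention: each axis is flipped
#' if needed so the sum of its environment loadings is nonnegative
#' (ties broken by making the first nonzero loading positive), so plots
#' do not mirror between runs.
#'
#' @param matrix a [trait_matrix] (g >= 2, e >= 2).
#' @param svp singular value partitioning mode.
#' @param n_axes number of retained axes for biplot-derived summaries
#'   (default 2); scores for all axes are kept for diagnostics.
#' @return A list of class `gge_model`: `centered`, `singular_values`,
#'   `genotype_scores`, `environment_scores` (all axes, partitioned),
#'   `var_explained` (fractions, all axes), `svp`, `n_axes`, labels and
#'   trait name.
#' @export
fit_gge <- function(matrix, svp = c("genotype", "environment"), n_axes = 2) {
  svp <- match.arg(svp)
  m <- unclass(as.matrix(matrix))
  g <- nrow(m); e <- ncol(m)
  if (g < 2 || e < 2) stop("need g >= 2 and e >= 2", call. = FALSE)
  if (n_axes < 1 || n_axes > min(g, e)) {
    stop("n_axes must lie in [1, min(g, e)]", call. = FALSE)
  }
  centered <- center_environment(m)
  sv <- svd(centered)
  # deterministic axis orientation
  for (k in seq_along(sv$d)) {
    s <- sum(sv$v[, k])
    if (s == 0) {
      nz <- which(sv$v[, k] != 0)
      s <- if (length(nz)) sv$v[nz[1], k] else 1
    }
    if (s < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  lam <- sv$d
  if (svp == "genotype") {
    gs <- sv$u %*% diag(lam, length(lam))
    es <- sv$v
  } else {
    gs <- sv$u
    es <- sv$v %*% diag(lam, length(lam))
  }
  gl <- rownames(m) %||% paste0("G", seq_len(g))
  el <- colnames(m) %||% paste0("E", seq_len(e))
  dimnames(gs) <- list(gl, paste0("PC", seq_along(lam)))
  dimnames(es) <- list(el, paste0("PC", seq_along(lam)))
  tot <- sum(lam^2)
  structure(list(centered = centered,
                 singular_values = lam,
                 genotype_scores = gs,
                 environment_scores = es,
                 var_explained = if (tot > 0) lam^2 / tot else rep(0, length(lam)),
                 svp = svp, n_axes = as.integer(n_axes),
                 genotype_labels = gl, environment_labels = el,
                 trait = attr(matrix, "trait_name") %||% "trait"),
            class = "gge_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gge_model <- function(x, ...) {
  cat("GGE model (", x$svp, "-focused SVP): ",
      length(x$genotype_labels), " genotypes x ",
      length(x$environment_labels), " environments\n", sep = "")
  ve <- round(100 * x$var_explained[seq_len(x$n_axes)], 2)
  cat("Retained axes: ", x$n_axes, " (", paste0(ve, "%", collapse = " + "),
      " = ", round(sum(ve), 2), "% of G+GE)\n", sep = "")
  invisible(x)
}

# internal: retained 2-D scores
scores2 <- function(model, what = c("genotype", "environment")) {
  what <- match.arg(what)
  s <- if (what == "genotype") model$genotype_scores else model$environment_scores
  if (ncol(s) < 2) stop("need at least 2 axes", call. = FALSE)
  s[, 1:2, drop = FALSE]
}

#' Average environment coordination frame
#'
#' The AEC abscissa is the unit vector from the biplot origin toward the
#' mean of the environment scores; the ordinate is its 90-degree
#' counter-clockwise rotation. Projections on the abscissa proxy mean
#' performance; perpendicular projections proxy instability.
#'
#' @param model a 2-axis (or more) [fit_gge()] model.
#' @return List of class `aec_frame` with `average_environment`,
#'   `abscissa`, `ordinate` (each length 2).
#' @export
aec_frame <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  avg <- unname(colMeans(scores2(model, "environment")))
  nrm <- sqrt(sum(avg^2))
  if (nrm < 1e-12) {
    stop("degenerate AEC frame: average environment at the origin",
         call. = FALSE)
  }
  a <- avg / nrm
  structure(list(average_environment = avg, abscissa = a,
                 ordinate = c(-a[2], a[1])),
            class = "aec_frame")
}

#' Mean performance vs. stability along the AEC
#'
#' Projects genotype scores onto the AEC frame: the abscissa projection
#' is the mean-performance proxy, the signed ordinate projection the
#' stability measure (genotypes with longer perpendicular vectors from
#' the abscissa are less stable).
#'
#' @param model a genotype-focused [fit_gge()] model.
#' @param frame optional [aec_frame()]; computed from `model` when
#'   omitted.
#' @return Data frame with `genotype`, `mean_proxy`, `stability`,
#'   ordered as the model's genotypes.
#' @export
mean_stability <- function(model, frame = NULL) {
  stopifnot(inherits(model, "gge_model"))
  if (model$svp != "genotype") {
    stop("mean-vs-stability uses the genotype-focused SVP", call. = FALSE)
  }
  if (is.null(frame)) frame <- aec_frame(model)
  gs <- scores2(model, "genotype")
  data.frame(genotype = model$genotype_labels,
             mean_proxy = unname(drop(gs %*% frame$abscissa)),
             stability = unname(drop(gs %*% frame$ordinate)),
             stringsAsFactors = FALSE)
}

#' Rank genotypes by distance to the ideal genotype
#'
#' The ideal genotype sits at the maximal mean-performance projection
#' with zero instability, i.e. at `(max(mean_proxy), 0)` in AEC
#' coordinates; genotypes are ranked by Euclidean distance to it.
#'
#' @param ms output of [mean_stability()].
#' @return `ms` with `distance` and `rank` columns appended (rank 1 =
#'   closest to ideal).
#' @export
rank_vs_ideal <- function(ms) {
  stopifnot(all(c("mean_proxy", "stability") %in% names(ms)))
  if (all(ms$mean_proxy <= 0)) {
    warning("no genotype with positive mean projection; ",
            "ideal defined at the maximum regardless", call. = FALSE)
  }
  ideal <- c(max(ms$mean_proxy), 0)
  ms$distance <- sqrt((ms$mean_proxy - ideal[1])^2 + ms$stability^2)
  ms$rank <- rank(ms$distance, ties.method = "first")
  ms
}

#' Discriminating power, representativeness and desirability of test
#' environments
#'
#' Each environment vector's length is its discriminating power; the
#' cosine of its angle with the AEC abscissa is its representativeness;
#' the default desirability is their product, i.e. the projection of the
#' environment vector onto the average-environment axis.
#'
#' @param model an environment-focused [fit_gge()] model.
#' @param frame optional [aec_frame()].
#' @param desirability_rule `"projection"` (length x cosine, default) or
#'   `"product_rank"` (rank-sum of the two criteria, smaller = better,
#'   offered as an alternative ordering).
#' @return Data frame with `environment`, `discriminating_power`,
#'   `representativeness`, `desirability`; zero-length vectors get `NA`
#'   representativeness and are flagged in a `degenerate` column.
#' @export
environment_metrics <- function(model, frame = NULL,
                                desirability_rule = c("projection",
                                                      "product_rank")) {
  stopifnot(inherits(model, "gge_model"))
  desirability_rule <- match.arg(desirability_rule)
  if (model$svp != "environment") {
    stop("environment evaluation uses the environment-focused SVP",
         call. = FALSE)
  }
  if (is.null(frame)) frame <- aec_frame(model)
  es <- scores2(model, "environment")
  len <- sqrt(rowSums(es^2))
  proj <- drop(es %*% frame$abscissa)
  rep_ <- ifelse(len > 0, proj / len, NA_real_)
  desir <- switch(desirability_rule,
                  projection = len * rep_,
                  product_rank = rank(-len) + rank(-rep_))
  data.frame(environment = model$environment_labels,
             discriminating_power = len,
             representativeness = rep_,
             desirability = desir,
             degenerate = len == 0,
             stringsAsFactors = FALSE)
}

#' Which-won-where mega-environment delineation
#'
#' Draws the convex hull around the genotype scores in the retained
#' 2-D space, splits the plane into sectors by rays from the origin
#' perpendicular to each hull edge, and assigns every environment to the
#' sector containing its score direction. The hull vertex between a
#' sector's bounding rays maximizes the inner product with every
#' direction in that sector, so it is the winning genotype for all
#' environments falling there; environments sharing a sector form a
#' mega-environment.
#'
#' @param model a genotype-focused 2-axis [fit_gge()] model with at
#'   least 3 non-collinear genotype score points.
#' @return List of class `www_result`: `hull_vertices` (counter-clockwise
#'   genotype labels), `sectors` (data frame of vertex and bounding ray
#'   angles, radians in `[0, 2pi)`), `assignment` (per environment:
#'   winning vertex, sector angles, boundary flag), and
#'   `mega_environments` (winner -> environment labels).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  if (model$svp != "genotype") {
    stop("which-won-where uses the genotype-focused SVP", call. = FALSE)
  }
  gs <- scores2(model, "genotype")
  es <- scores2(model, "environment")
  hull <- rev(grDevices::chull(gs))            # counter-clockwise order
  if (length(hull) < 3) {
    stop("degenerate hull: genotype points are collinear or coincident",
         call. = FALSE)
  }
  v <- gs[hull, , drop = FALSE]
  m <- nrow(v)
  nxt <- c(2:m, 1)
  edges <- v[nxt, ] - v
  # outward normal of each CCW edge: boundary ray between the adjacent
  # vertices' normal cones
  normals <- cbind(edges[, 2], -edges[, 1])
  ray_angle <- atan2(normals[, 2], normals[, 1]) %% (2 * pi)
  # sector of vertex k runs CCW from the ray of edge (k-1, k) to the ray
  # of edge (k, k+1); an exact boundary hit goes to the CCW sector
  prv <- c(m, 1:(m - 1))
  sectors <- data.frame(vertex = model$genotype_labels[hull],
                        start_angle = ray_angle[prv],
                        end_angle = ray_angle,
                        stringsAsFactors = FALSE)
  in_sector <- function(theta, a, b) {
    if (a <= b) theta >= a & theta < b else theta >= a | theta < b
  }
  env_len <- sqrt(rowSums(es^2))
  env_theta <- atan2(es[, 2], es[, 1]) %% (2 * pi)
  tol <- 1e-9
  winner <- character(nrow(es)); boundary <- logical(nrow(es))
  for (j in seq_len(nrow(es))) {
    if (env_len[j] < tol) {
      winner[j] <- NA_character_
      next
    }
    th <- env_theta[j]
    boundary[j] <- any(abs(((th - ray_angle + pi) %% (2 * pi)) - pi) < tol)
    hit <- which(mapply(in_sector, a = sectors$start_angle,
                        b = sectors$end_angle, MoreArgs = list(theta = th)))
    winner[j] <- sectors$vertex[hit[1]]
  }
  assignment <- data.frame(environment = model$environment_labels,
                           winner = winner,
                           on_boundary = boundary,
                           at_origin = env_len < tol,
                           stringsAsFactors = FALSE)
  ok <- !is.na(winner)
  mega <- split(model$environment_labels[ok], winner[ok])
  structure(list(hull_vertices = model$genotype_labels[hull],
                 sectors = sectors,
                 assignment = assignment,
                 mega_environments = mega),
            class = "www_result")
}

#' @export
print.www_result <- function(x, ...) {
  cat("Which-won-where:", length(x$hull_vertices), "hull vertices,",
      length(x$mega_environments), "mega-environment(s)\n")
  for (w in names(x$mega_environments)) {
    cat("  winner ", w, ": ",
        paste(x$mega_environments[[w]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Ward hierarchical clustering of genotypes or environments
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances of (optionally z-scored) feature rows, as used to
#' group genotypes on their trait means and locations on their genotype
#' profiles. Backed by `stats::hclust(method = "ward.D2")`, whose merge
#' heights satisfy `height^2 = 2 x increase in within-cluster error sum
#' of squares`.
#'
#' @param features items x features numeric matrix or data frame with
#'   item rownames.
#' @param k number of clusters to cut (1 <= k <= items).
#' @param standardize z-score feature columns first (default `TRUE`);
#'   zero-variance columns are left centered only.
#' @return List of class `ward_clustering`: `cluster` (named membership
#'   vector), `k`, `merge`, `height`, and the underlying `hclust` tree.
#' @export
ward_cluster <- function(features, k, standardize = TRUE) {
  x <- as.matrix(features)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("features must be finite numeric", call. = FALSE)
  }
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must lie in [1, items]", call. = FALSE)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    x <- sweep(x, 2, colMeans(x))
    x <- sweep(x, 2, ifelse(sds > 0, sds, 1), "/")
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(cluster = stats::cutree(hc, k = k), k = as.integer(k),
                 merge = hc$merge, height = hc$height, hclust = hc),
            class = "ward_clustering")
}
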