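# fabricate a minimal gge_model with prescribed 2-D scores, for testing
# the AEC-frame and downstream geometry in isolation
fake_model <- function(gs, es, svp = "genotype") {
  gs <- as.matrix(gs); es <- as.matrix(es)
  gl <- paste0("G", seq_len(nrow(gs)))
  el <- paste0("E", seq_len(nrow(es)))
  dimnames(gs) <- list(gl, paste0("PC", seq_len(ncol(gs))))
  dimnames(es) <- list(el, paste0("PC", seq_len(ncol(es))))
  structure(list(genotype_scores = gs, environment_scores = es,
                 svp = svp, n_axes = 2L,
                 genotype_labels = gl, environment_labels = el),
            class = "gge_model")
}

test_that("environment centering removes column means and is idempotent", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  cm <- center_environment(m)
  expect_equal(cm, matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(center_environment(cm), cm)
  # column-constant matrix is annihilated
  expect_true(all(center_environment(matrix(5, 4, 3)) == 0))
  const <- matrix(rep(c(2, 7, 1), each = 4), 4, 3)
  expect_true(all(abs(center_environment(const)) < 1e-12))
})

test_that("singular values and variance explained follow the SVD", {
  tw <- trait_matrix(matrix(c(1, 3, 2, 4), 2, 2))
  mod <- fit_gge(tw, n_axes = 2)
  # centered [[-1,-1],[1,1]]: cross-product eigenvalues (4, 0)
  expect_equal(mod$singular_values, c(2, 0))
  expect_equal(mod$var_explained[1], 1)
  # rank-1 matrix: first axis explains everything
  r1 <- trait_matrix(outer(rnorm(5), rnorm(3)))
  expect_equal(fit_gge(r1)$var_explained[1], 1, tolerance = 1e-12)
})

test_that("full-rank score product reconstructs the centered matrix", {
  tw <- random_matrix(5, 4, seed = 8)
  for (svp in c("genotype", "environment")) {
    mod <- fit_gge(tw, svp = svp, n_axes = 4)
    recon <- mod$genotype_scores %*% t(mod$environment_scores)
    expect_lt(max(abs(recon - mod$centered)), 1e-10)
  }
})

test_that("variance explained is invariant to the SVP mode", {
  tw <- random_matrix(6, 4, seed = 15)
  expect_equal(fit_gge(tw, "genotype")$var_explained,
               fit_gge(tw, "environment")$var_explained)
})

test_that("axis sign convention makes environment loading sums nonnegative", {
  for (s in 1:10) {
    mod <- fit_gge(random_matrix(6, 4, seed = 100 + s), "genotype")
    v <- mod$environment_scores   # svp=genotype: env scores are V columns
    pos <- colSums(v) >= -1e-12
    expect_true(all(pos))
  }
})

test_that("AEC frame is the normalized mean environment direction", {
  m <- fake_model(gs = diag(2), es = rbind(c(1, 0), c(1, 0)))
  fr <- aec_frame(m)
  expect_equal(fr$abscissa, c(1, 0))
  expect_equal(fr$ordinate, c(0, 1))
  m2 <- fake_model(gs = diag(2), es = rbind(c(1, 1), c(1, -1)))
  expect_equal(aec_frame(m2)$abscissa, c(1, 0))
  # duplication of every environment point leaves the frame unchanged
  m3 <- fake_model(gs = diag(2), es = rbind(c(1, 1), c(1, -1),
                                            c(1, 1), c(1, -1)))
  expect_equal(aec_frame(m3), aec_frame(m2))
  expect_equal(sum(aec_frame(m2)$abscissa * aec_frame(m2)$ordinate), 0)
  # degenerate: average environment at the origin
  m0 <- fake_model(gs = diag(2), es = rbind(c(1, 0), c(-1, 0)))
  expect_error(aec_frame(m0), "degenerate")
})

test_that("mean/stability are axis-aligned projections on the AEC", {
  m <- fake_model(gs = rbind(c(0, 0), c(3, 4)),
                  es = rbind(c(1, 0), c(1, 0)))
  ms <- mean_stability(m)
  expect_equal(ms$mean_proxy, c(0, 3))
  expect_equal(ms$stability, c(0, 4))
  expect_error(mean_stability(fake_model(diag(2), diag(2),
                                         svp = "environment")),
               "genotype-focused")
})

test_that("zero planted G-by-E collapses all stabilities to zero", {
  d <- simulate_met(sim_config(g = 8, e = 4, r = 1, mu = 30, var_g = 25,
                               var_e = 9, var_ge = 0, var_err = 0,
                               seed = 19))
  mod <- fit_gge(to_two_way(d, "sim"), "genotype")
  ms <- mean_stability(mod)
  expect_lt(max(abs(ms$stability)), 1e-9)
  expect_equal(mod$var_explained[1], 1, tolerance = 1e-12)
})

test_that("distance to ideal and ranking follow Euclidean geometry", {
  m <- fake_model(gs = rbind(c(4, 0), c(1, 4), c(2, 0)),
                  es = rbind(c(1, 0), c(1, 0)))
  rk <- rank_vs_ideal(mean_stability(m))
  expect_equal(rk$distance, c(0, 5, 2))   # 3-4-5 triangle for G2
  expect_equal(rk$rank, c(1, 3, 2))
  # ranking is invariant under rigid rotation of all scores
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  m_rot <- fake_model(gs = m$genotype_scores %*% t(R),
                      es = m$environment_scores %*% t(R))
  rk_rot <- rank_vs_ideal(mean_stability(m_rot))
  expect_equal(rk_rot$distance, rk$distance)
  expect_equal(rk_rot$rank, rk$rank)
})

test_that("all-nonpositive mean projections warn but still rank", {
  m <- fake_model(gs = rbind(c(-1, 0), c(-2, 1)),
                  es = rbind(c(1, 0), c(1, 0)))
  expect_warning(rk <- rank_vs_ideal(mean_stability(m)), "ideal")
  expect_equal(rk$rank[1], 1)
})

test_that("environment metrics follow vector length and angle", {
  m <- fake_model(gs = diag(2), es = rbind(c(5, 0), c(3, 4)),
                  svp = "environment")
  fr <- structure(list(average_environment = c(1, 0), abscissa = c(1, 0),
                       ordinate = c(0, 1)), class = "aec_frame")
  em <- environment_metrics(m, fr)
  expect_equal(em$discriminating_power, c(5, 5))
  expect_equal(em$representativeness, c(1, 0.6))
  expect_equal(em$desirability, c(5, 3))
  expect_error(environment_metrics(fake_model(diag(2), diag(2))),
               "environment-focused")
})

test_that("desirability is monotone in representativeness at fixed length", {
  th <- seq(0, pi / 2, length.out = 5)
  es <- 4 * cbind(cos(th), sin(th))     # equal lengths, rising angle
  m <- fake_model(gs = diag(2), es = es, svp = "environment")
  fr <- structure(list(average_environment = c(1, 0), abscissa = c(1, 0),
                       ordinate = c(0, 1)), class = "aec_frame")
  em <- environment_metrics(m, fr)
  expect_true(all(diff(em$desirability) < 0))  # falls as cosine falls
})

test_that("square-hull worked example yields two mega-environments", {
  gs <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1), c(0, 0))
  es <- rbind(c(1, 0.1), c(-1, -0.1))
  m <- fake_model(gs, es)
  www <- which_won_where(m)
  expect_equal(www$assignment$winner, c("G1", "G3"))
  expect_length(www$mega_environments, 2)
  # single environment: exactly one mega-environment
  www1 <- which_won_where(fake_model(gs, es[1, , drop = FALSE]))
  expect_length(www1$mega_environments, 1)
})

test_that("sector winners equal brute-force inner-product argmax", {
  for (s in 1:25) {
    mod <- fit_gge(random_matrix(10, 4, seed = 2000 + s), "genotype")
    www <- which_won_where(mod)
    expect_equal(www$assignment$winner, unname(brute_force_winners(mod)),
                 info = paste("instance", s))
    expect_true(all(www$assignment$winner %in% www$hull_vertices))
  }
})

test_that("degenerate genotype geometry raises a hull error", {
  gs <- cbind(1:4, 2 * (1:4))           # collinear points
  expect_error(which_won_where(fake_model(gs, rbind(c(1, 0)))),
               "degenerate hull")
})

test_that("planted crossover partition is recovered exactly", {
  cfg <- sim_config(g = 10, e = 4, r = 1, mu = 0, var_g = 0, var_e = 0,
                    var_ge = 80, var_err = 0,
                    crossover = crossover_spec(2), seed = 55)
  mod <- fit_gge(to_two_way(simulate_met(cfg), "sim"), "genotype")
  # rank-1 crossover plus no noise: 2 axes carry 100% of variation
  expect_equal(sum(mod$var_explained[1:2]), 1, tolerance = 1e-12)
  www <- which_won_where(mod)
  got <- lapply(unname(www$mega_environments), sort)
  truth <- lapply(plant_crossover_truth(cfg), sort)
  expect_setequal(got, truth)
})

test_that("Ward clustering recovers separated clouds and cuts to singletons", {
  set.seed(4)
  x <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 20), 5, 2))
  rownames(x) <- paste0("it", 1:10)
  wc <- ward_cluster(x, k = 2, standardize = FALSE)
  expect_length(unique(wc$cluster[1:5]), 1)
  expect_length(unique(wc$cluster[6:10]), 1)
  expect_false(wc$cluster[1] == wc$cluster[10])
  expect_equal(sort(unique(ward_cluster(x, k = 10)$cluster)), 1:10)
  expect_error(ward_cluster(x, k = 11), "k must")
})

test_that("merge heights match the Ward criterion recomputed from scratch", {
  set.seed(31)
  x <- matrix(rnorm(12), 6, 2)
  # oracle: greedy agglomeration minimizing the increase in
  # within-cluster error sum of squares at each merge
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
  }
  cl <- as.list(1:6)
  oracle_heights <- numeric(0)
  while (length(cl) > 1) {
    best <- Inf; pick <- NULL
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      dcost <- ess(c(cl[[i]], cl[[j]])) - ess(cl[[i]]) - ess(cl[[j]])
      if (dcost < best) { best <- dcost; pick <- c(i, j) }
    }
    oracle_heights <- c(oracle_heights, best)
    cl[[pick[1]]] <- c(cl[[pick[1]]], cl[[pick[2]]])
    cl[[pick[2]]] <- NULL
  }
  wc <- ward_cluster(x, k = 1, standardize = FALSE)
  # heights are sqrt(2 x ESS increase) and nondecreasing
  expect_equal(wc$height^2, 2 * oracle_heights, tolerance = 1e-10)
  expect_true(all(diff(wc$height) >= -1e-12))
})
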