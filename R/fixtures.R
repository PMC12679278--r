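#' Packaged grasspea multilocation trial summaries
#'
#' Small plain-text fixtures transcribed from a published 64-genotype,
#' 4-location grasspea (Lathyrus sativus) winter trial: per-genotype
#' means of days to maturity (DTM, days), biological yield (BY, t/ha),
#' seed yield (SY, kg/ha) and the published multi-trait selection index
#' (BLPSI); per-location means; the trial's published ANOVA mean squares
#' with percent contributions; published genetic parameters; and footer
#' summaries (LSD, CV, variance components). The published BLPSI column
#' is carried as data — its weighting is not recoverable from the
#' printed trait means.
#'
#' @return `grasspea_genotype_means()` and `grasspea_location_means()`
#'   return data frames of means; `grasspea_anova_ms()` the published
#'   mean squares per trait and source; `grasspea_genetic_params()` the
#'   published genetic-parameter table; `grasspea_trait_summary()` the
#'   LSD/CV/variance footer rows.
#' @name grasspea_fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "metgge")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}

#' @rdname grasspea_fixtures
#' @export
grasspea_genotype_means <- function() {
  utils::read.csv(fixture_path("grasspea_genotype_means.csv"),
                  check.names = FALSE)
}

#' @rdname grasspea_fixtures
#' @export
grasspea_location_means <- function() {
  utils::read.csv(fixture_path("grasspea_location_means.csv"),
                  check.names = FALSE)
}

#' @rdname grasspea_fixtures
#' @export
grasspea_anova_ms <- function() {
  utils::read.csv(fixture_path("grasspea_anova_ms.csv"),
                  check.names = FALSE)
}

#' @rdname grasspea_fixtures
#' @export
grasspea_genetic_params <- function() {
  utils::read.csv(fixture_path("grasspea_genetic_params.csv"),
                  check.names = FALSE)
}

#' @rdname grasspea_fixtures
#' @export
grasspea_trait_summary <- function() {
  utils::read.csv(fixture_path("grasspea_trait_summary.csv"),
                  check.names = FALSE)
}

#' Copy the packaged fixtures into a directory
#'
#' Writes the fixture CSVs to `out_dir` together with a
#' `fixtures_manifest.csv` of md5 checksums, for use by external
#' analysis scripts and acceptance checks.
#'
#' @param out_dir destination directory (created if absent).
#' @return Data frame manifest (file, md5), invisibly.
#' @export
make_fixtures <- function(out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("grasspea_genotype_means.csv", "grasspea_location_means.csv",
             "grasspea_anova_ms.csv", "grasspea_genetic_params.csv",
             "grasspea_trait_summary.csv")
  dest <- file.path(out_dir, files)
  ok <- file.copy(vapply(files, fixture_path, ""), dest, overwrite = TRUE)
  if (!all(ok)) stop("fixture copy failed", call. = FALSE)
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(dest)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(out_dir, "fixtures_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
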