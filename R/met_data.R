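#' Construct a multi-environment trial dataset
#'
#' A `met_dataset` is a long-format data frame of plot-level (or
#' genotype-mean) observations with one row per
#' (genotype, environment, replicate) record and one numeric column per
#' trait. Label order is the insertion order of first appearance and is
#' preserved by every downstream operation.
#'
#' @param data data frame with columns `genotype`, `environment`,
#'   `replicate` followed by numeric trait columns.
#' @param traits character vector naming the trait columns; defaults to all
#'   columns other than the three identifier columns.
#' @return An object of class `met_dataset` (a data frame with attributes
#'   `trait_names`, `genotype_order`, `environment_order`).
#' @examples
#' d <- data.frame(genotype = rep(c("A", "B"), each = 2),
#'                 environment = rep(c("E1", "E2"), 2),
#'                 replicate = 1, yield = c(10, 12, 14, 16))
#' met_dataset(d)
#' @export
met_dataset <- function(data, traits = NULL) {
  data <- as.data.frame(data)
  id_cols <- c("genotype", "environment", "replicate")
  missing_cols <- setdiff(id_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) traits <- setdiff(names(data), id_cols)
  if (length(traits) == 0) stop("no trait columns found", call. = FALSE)
  absent <- setdiff(traits, names(data))
  if (length(absent) > 0) {
    stop("declared trait column(s) not present: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (col in id_cols) data[[col]] <- trimws(as.character(data[[col]]))
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      stop("trait '", tr, "' is not numeric (first offending row: ",
           if (length(bad)) bad[1] else NA, ")", call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("trait '", tr, "' contains non-finite values (row ",
           which(!is.finite(v))[1], ")", call. = FALSE)
    }
  }
  key <- paste(data$genotype, data$environment, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (genotype, environment, replicate) record: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }
  structure(
    data[, c(id_cols, traits)],
    trait_names = traits,
    genotype_order = unique(data$genotype),
    environment_order = unique(data$environment),
    class = c("met_dataset", "data.frame")
  )
}

#' @export
print.met_dataset <- function(x, ...) {
  cat("MET dataset: ", length(attr(x, "genotype_order")), " genotypes x ",
      length(attr(x, "environment_order")), " environments, ",
      nrow(x), " records\n", sep = "")
  cat("Traits:", paste(attr(x, "trait_names"), collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Read a long-format MET CSV file
#'
#' The canonical interchange format is a UTF-8 CSV with a header row and
#' columns `genotype`, `environment`, `replicate` followed by one numeric
#' column per trait ("." decimal separator). Alternative column names can
#' be mapped through `schema`.
#'
#' @param path path to the CSV file.
#' @param schema named character vector mapping the canonical names
#'   (`genotype`, `environment`, `replicate`) to the column names used in
#'   the file.
#' @param traits optional character vector of trait column names (file
#'   names, not canonical names); defaults to every remaining column.
#' @return A [met_dataset].
#' @export
read_met_csv <- function(path,
                         schema = c(genotype = "genotype",
                                    environment = "environment",
                                    replicate = "replicate"),
                         traits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  for (canon in c("genotype", "environment", "replicate")) {
    src <- if (canon %in% names(schema)) schema[[canon]] else canon
    if (!src %in% names(raw)) {
      stop("schema error: column '", src, "' (", canon,
           ") not present in ", path, call. = FALSE)
    }
    names(raw)[names(raw) == src] <- canon
  }
  met_dataset(raw, traits = traits)
}

#' Write a MET dataset as long-format CSV
#'
#' @param dataset a [met_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "met_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a genotype-by-environment trait matrix
#'
#' @param values numeric g x e matrix of cell means.
#' @param trait name of the trait the cells hold.
#' @return A `trait_matrix`: a numeric matrix with genotype rownames,
#'   environment colnames and a `trait_name` attribute.
#' @export
trait_matrix <- function(values, trait = "trait") {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("trait matrix must be nonempty", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("trait matrix has missing cells",
                                    call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("E", seq_len(ncol(values)))
  structure(values, trait_name = trait,
            class = c("trait_matrix", class(values)))
}

#' Read a wide genotype-by-environment CSV as a trait matrix
#'
#' First column holds genotype labels, remaining columns one environment
#' each. Wide CSV is read-only; the long format is canonical.
#'
#' @param path path to the CSV file.
#' @param trait trait name to attach.
#' @return A [trait_matrix].
#' @export
read_two_way_csv <- function(path, trait = "trait") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  g <- trimws(as.character(raw[[1]]))
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- g
  trait_matrix(m, trait = trait)
}

#' Collapse a MET dataset into a two-way table of cell means
#'
#' Averages replicate observations within each (genotype, environment)
#' cell. This is the two-way table that the GGE model decomposes; label
#' order follows the dataset.
#'
#' @param dataset a [met_dataset].
#' @param trait trait name to tabulate.
#' @param aggregator cell aggregator; only `"mean"` is supported.
#' @return A [trait_matrix] of cell means.
#' @export
to_two_way <- function(dataset, trait, aggregator = "mean") {
  stopifnot(inherits(dataset, "met_dataset"))
  aggregator <- match.arg(aggregator, "mean")
  if (!trait %in% attr(dataset, "trait_names")) {
    stop("trait '", trait, "' not in dataset", call. = FALSE)
  }
  gl <- attr(dataset, "genotype_order")
  el <- attr(dataset, "environment_order")
  gf <- factor(dataset$genotype, levels = gl)
  ef <- factor(dataset$environment, levels = el)
  counts <- table(gf, ef)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)
    cells <- paste(gl[empty[, 1]], el[empty[, 2]], sep = ":")
    stop("empty (genotype, environment) cell(s): ",
         paste(utils::head(cells, 10), collapse = ", "), call. = FALSE)
  }
  sums <- tapply(dataset[[trait]], list(gf, ef), sum)
  m <- sums / as.matrix(counts)
  trait_matrix(m[gl, el, drop = FALSE], trait = trait)
}

#' Check replicate balance of a MET dataset
#'
#' A dataset is balanced when every (genotype, environment) cell carries
#' the same replicate count r. ANOVA and the GGE engine require balance;
#' this is a report, not an exception.
#'
#' @param dataset a [met_dataset].
#' @return A list with elements `complete` (logical), `r` (common
#'   replicate count, `NA` when incomplete), and `offending_cells`
#'   (data frame of cells that deviate from the modal count).
#' @export
validate_balance <- function(dataset) {
  stopifnot(inherits(dataset, "met_dataset"))
  gl <- attr(dataset, "genotype_order")
  el <- attr(dataset, "environment_order")
  counts <- table(factor(dataset$genotype, levels = gl),
                  factor(dataset$environment, levels = el))
  complete <- length(unique(as.vector(counts))) == 1
  r <- if (complete) as.integer(counts[1, 1]) else NA_integer_
  offending <- data.frame(genotype = character(), environment = character(),
                          n = integer())
  if (!complete) {
    tab <- table(as.vector(counts))
    modal <- as.integer(names(tab)[which.max(tab)])
    idx <- which(counts != modal, arr.ind = TRUE)
    offending <- data.frame(genotype = gl[idx[, 1]],
                            environment = el[idx[, 2]],
                            n = as.integer(counts[idx]))
  }
  structure(list(complete = complete, r = r, offending_cells = offending),
            class = "met_balance")
}

#' @export
print.met_balance <- function(x, ...) {
  if (x$complete) {
    cat("balanced layout: r =", x$r, "\n")
  } else {
    cat("unbalanced layout;", nrow(x$offending_cells), "offending cell(s)\n")
    print(x$offending_cells)
  }
  invisible(x)
}

# internal: dataset dimensions as a named list
met_dims <- function(dataset) {
  list(g = length(attr(dataset, "genotype_order")),
       e = length(attr(dataset, "environment_order")))
}
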