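# TSV readers/writers and run artifacts.  All matrix formats are plain
# tab-separated text with a header row and an ID first column; numbers are
# written with 17 significant digits so write/read round-trips are exact.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_tsv_matrix <- function(values, path, col_header, row_ids) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", col_header), collapse = "\t"), con)
  body <- apply(values, 1L, function(r) paste(.fmt_num(r), collapse = "\t"))
  writeLines(paste(row_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a longitudinal phenotype TSV
#'
#' Format: tab-separated, header row of numeric measurement times, first
#' column individual IDs.  Missing phenotypes are rejected.  If the header
#' times are not increasing, columns are re-sorted with a warning.
#'
#' @param path file path.
#' @return a [phenotype_panel()].
#' @export
read_phenotype <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          na.strings = character(0))
  times <- suppressWarnings(as.numeric(colnames(df)))
  if (anyNA(times))
    stop("non-numeric time labels in header: ",
         paste(colnames(df)[is.na(times)], collapse = ", "))
  if (anyDuplicated(times)) stop("duplicate times in header")
  vals <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  na_coded <- vapply(df, function(cl) toupper(trimws(cl)) %in% c("NA", ""),
                     logical(nrow(df)))
  if (!is.matrix(na_coded)) na_coded <- matrix(na_coded, nrow = nrow(df))
  bad <- which(is.na(vals) & !na_coded, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric phenotype at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  if (anyNA(vals)) stop("missing phenotypes unsupported")
  rownames(vals) <- rownames(df)
  if (is.unsorted(times, strictly = TRUE)) {
    warning("header times out of order; columns re-sorted")
    o <- order(times)
    times <- times[o]
    vals <- vals[, o, drop = FALSE]
  }
  phenotype_panel(vals, times)
}

#' Write a phenotype panel as TSV
#' @param panel a [phenotype_panel()].
#' @param path output path.
#' @export
write_phenotype <- function(panel, path) {
  stopifnot(inherits(panel, "phenotype_panel"))
  .write_tsv_matrix(panel$values, path, .fmt_num(panel$times), panel$ids)
}

#' Read a square relationship matrix TSV
#' @param path file path (header = IDs, first column = IDs).
#' @return symmetric numeric matrix.
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  G <- as.matrix(df)
  if (anyNA(G) || !is.numeric(G)) stop("relationship matrix contains non-numeric cells")
  .check_relmat(G)
}

#' Write a relationship matrix as TSV
#' @param G square matrix with ID dimnames (generated if absent).
#' @param path output path.
#' @export
write_grm <- function(G, path) {
  G <- .check_relmat(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(G)))
  .write_tsv_matrix(G, path, ids, ids)
}

#' Read a genotype matrix TSV
#'
#' Tab-separated, header row of marker IDs, first column individual IDs;
#' missing genotypes encoded as `NA` or an empty cell.
#'
#' @param path file path.
#' @return numeric matrix with possible `NA`s (run [impute_missing()] next).
#' @export
read_genotype <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, na.strings = c("NA", ""))
  g <- as.matrix(df)
  storage.mode(g) <- "double"
  .check_geno(g, allow_missing = TRUE)
}

#' Write a genotype matrix as TSV
#' @param geno genotype matrix (NAs allowed).
#' @param path output path.
#' @export
write_genotype <- function(geno, path) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
  markers <- .marker_names(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", markers), collapse = "\t"), con)
  body <- apply(geno, 1L, function(r)
    paste(ifelse(is.na(r), "NA", .fmt_num(r)), collapse = "\t"))
  writeLines(paste(ids, body, sep = "\t"), con)
  invisible(path)
}

.write_summary_tsv <- function(summary_df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time\tmean\tlower95\tupper95", con)
  writeLines(paste(.fmt_num(summary_df$time), .fmt_num(summary_df$mean),
                   .fmt_num(summary_df$lower95), .fmt_num(summary_df$upper95),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a summary-curve TSV written by [write_results()]
#' @param path file path.
#' @return data.frame with columns time, mean, lower95, upper95.
#' @export
read_summary <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Write run artifacts
#'
#' Writes per-component summary TSVs (time, mean, lower95, upper95), the full
#' draw matrices as gzip TSV when `draws` is given, and a JSON metadata file
#' echoing the seed and configuration plus final acceptance rates, then
#' returns the manifest of files written.
#'
#' @param draws a `posterior_draws` object, or `NULL` (two-stage runs).
#' @param summaries list of summary data.frames (`sigma2_G`, `sigma2_E`, `h2`).
#' @param config list echoed into the metadata; must contain `seed`.
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths written.
#' @export
write_results <- function(draws, summaries, config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  manifest <- character(0)
  for (nm in names(summaries)) {
    p <- file.path(out_dir, paste0("summary_", nm, ".tsv"))
    .write_summary_tsv(summaries[[nm]], p)
    manifest <- c(manifest, p)
  }
  meta <- list(package_version = as.character(utils::packageVersion("dynherit")),
               config = config, seed = config$seed)
  if (!is.null(draws)) {
    stopifnot(inherits(draws, "posterior_draws"))
    for (nm in c("sigma2_G", "sigma2_E", "h2")) {
      p <- file.path(out_dir, paste0("draws_", nm, ".tsv.gz"))
      con <- gzfile(p, "w")
      utils::write.table(format(draws[[nm]], digits = 17, trim = TRUE),
                         con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = .fmt_num(draws$meta$times))
      close(con)
      manifest <- c(manifest, p)
    }
    p <- file.path(out_dir, "draws_lambda.tsv.gz")
    con <- gzfile(p, "w")
    utils::write.table(data.frame(lambda_G = .fmt_num(draws$lambda_G),
                                  lambda_E = .fmt_num(draws$lambda_E)),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest <- c(manifest, p)
    meta <- c(meta, draws$meta[c("iterations", "burnin", "thin", "scale_factor",
                                 "accept_rate_lambda_E", "accept_rate_lambda_G")])
  }
  p <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- c(manifest, p)
  manifest
}

# Console/file logger used by the MCMC drivers.
.make_logger <- function(config) {
  every <- config$progress_every
  if (is.null(every)) every <- 1000L
  verbose <- isTRUE(config$verbose)
  log_file <- config$log_file
  list(every = as.integer(every),
       log = function(msg) {
         line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", msg)
         if (verbose) message(line)
         if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
       })
}
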