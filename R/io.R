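#' Write a simulated field as TIFF pair plus truth sidecar
#'
#' Writes `<prefix>_dapi.tif` and `<prefix>_marker.tif` as single-channel
#' grayscale TIFFs at the field's bit depth (intensities rounded to the
#' nearest integer level) and `<prefix>_truth.json` with the ground-truth
#' record.
#'
#' @param field a `"nuclei_field"` from [simulate_nuclei_field()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_field <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "nuclei_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bits <- field$truth$bit_depth
  max_int <- 2^bits - 1
  paths <- c(dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
             marker = file.path(dir, paste0(prefix, "_marker.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  tiff::writeTIFF(round(field$dapi) / max_int, paths[["dapi"]],
                  bits.per.sample = bits)
  tiff::writeTIFF(round(field$marker) / max_int, paths[["marker"]],
                  bits.per.sample = bits)
  truth <- field$truth
  truth$centers <- unname(split(truth$centers, row(truth$centers)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a single-channel grayscale TIFF as an intensity matrix
#'
#' @param path TIFF file path.
#' @param bit_depth bit depth used to rescale the `[0, 1]` TIFF samples back
#'   to integer intensity units.
#' @return A numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @export
read_channel_tiff <- function(path, bit_depth = 16) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(x * (2^bit_depth - 1))
}

#' Read / write a gene-by-sample count matrix as TSV
#'
#' The TSV layout is a `gene_id` first column followed by one column per
#' sample.
#'
#' @param counts integer matrix with gene row names and sample column names.
#' @param path file path.
#' @return `write_counts_tsv()` returns `path` invisibly; `read_counts_tsv()`
#'   returns the count matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character vectors, or a
#'   `"gene_set_collection"`.
#' @param path file path.
#' @param description description field written for every set.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` returns a
#'   named list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
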