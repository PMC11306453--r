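# Shared writer: "# key: value" metadata comment headers, then the
# delimited table.  Package version is always recorded so outputs carry
# enough provenance to re-run.
write_with_meta <- function(df, path, metadata = list(), delim = ",") {
  meta <- c(list(package = "mimpower",
                 version = as.character(utils::packageVersion("mimpower")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            metadata)
  lines <- sprintf("# %s: %s", names(meta),
                   vapply(meta, function(v) paste(format(v), collapse = " "),
                          character(1)))
  writeLines(lines, path)
  readr::write_delim(df, path, delim = delim, append = TRUE,
                     col_names = TRUE, na = "NA")
  invisible(path)
}

#' Write / read a genetic map as CSV
#'
#' Columns `marker`, `chromosome`, `position_cM` (pseudo loci are
#' excluded on write).  Metadata is stored as `# key: value` comment
#' lines.
#'
#' @param map Map tibble.
#' @param path File path.
#' @param metadata Named list for the comment header.
#' @export
write_map_csv <- function(map, path, metadata = list()) {
  map <- validate_map(map)
  write_with_meta(map[!map$pseudo, c("marker", "chromosome", "position_cM")],
                  path, metadata)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  map <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           chromosome = readr::col_character(),
                           position_cM = readr::col_double()))
  map$pseudo <- FALSE
  validate_map(map)
  map
}

#' Write / read phenotypes as CSV
#'
#' Columns `id` then one `<trait>_gkg` column per trait; the reader
#' strips the unit suffix back off.
#'
#' @param pheno Phenotype tibble (`id` plus trait columns, g/kg).
#' @param path File path.
#' @param metadata Named list for the comment header.
#' @export
write_pheno_csv <- function(pheno, path, metadata = list()) {
  out <- pheno
  tr <- setdiff(names(out), "id")
  names(out)[match(tr, names(out))] <- paste0(tr, "_gkg")
  write_with_meta(out, path, metadata)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(id = readr::col_character()))
  names(out) <- sub("_gkg$", "", names(out))
  out
}

#' Write a cross (map + genotypes + phenotypes) as a single CSV
#'
#' The cross CSV dialect: the header row holds the phenotype column
#' names (`id` first) followed by the marker ids; the second row is
#' blank under the phenotypes and holds each marker's chromosome; the
#' third row likewise holds the cM positions; every following row is one
#' individual, phenotype values then genotype codes `A`/`H`/`B` with
#' `-` for missing.  Marker columns are ordered by (chromosome,
#' position).  Writing then reading reproduces map, genotypes and
#' phenotypes exactly.
#'
#' @param cross A `ril_cross` (pseudomarkers are dropped on write).
#' @param path File path.
#' @param metadata Named list for the comment header.
#' @export
write_cross_csv <- function(cross, path, metadata = list()) {
  stopifnot(inherits(cross, "ril_cross"))
  cross <- drop_pseudomarkers(cross)
  map <- cross$map
  pheno <- cross$pheno
  if (is.null(pheno)) {
    pheno <- tibble::tibble(id = rownames(cross$geno))
  }
  stopifnot(identical(pheno$id, rownames(cross$geno)))
  n_ph <- ncol(pheno)
  codes <- geno_to_char(cross$geno)
  codes[is.na(codes)] <- "-"
  meta <- c(list(package = "mimpower",
                 version = as.character(utils::packageVersion("mimpower"))),
            metadata)
  lines <- c(
    sprintf("# %s: %s", names(meta), vapply(meta, format, character(1))),
    paste(c(names(pheno), map$marker), collapse = ","),
    paste(c(rep("", n_ph), map$chromosome), collapse = ","),
    paste(c(rep("", n_ph), format(map$position_cM, trim = TRUE)),
          collapse = ",")
  )
  ph_cells <- vapply(seq_len(nrow(pheno)), function(i) {
    paste(vapply(pheno[i, ], function(v) {
      if (is.numeric(v)) format(v, digits = 17, trim = TRUE) else as.character(v)
    }, character(1)), collapse = ",")
  }, character(1))
  body <- paste(ph_cells, apply(codes, 1, paste, collapse = ","), sep = ",")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a cross CSV
#'
#' @param path File path.
#' @return A `ril_cross`.
#' @rdname write_cross_csv
#' @export
read_cross_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 3) stop("malformed cross file: missing header rows",
                              call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  hdr <- cells[[1]]; chr_row <- cells[[2]]; pos_row <- cells[[3]]
  n_col <- length(hdr)
  pad <- function(x) c(x, rep("", n_col - length(x)))
  chr_row <- pad(chr_row); pos_row <- pad(pos_row)
  is_marker <- chr_row != ""
  n_ph <- match(TRUE, is_marker) - 1
  if (is.na(n_ph) || n_ph < 1 || any(!is_marker[(n_ph + 1):n_col])) {
    stop("malformed cross file: phenotype columns must precede a ",
         "contiguous marker block", call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(pos_row[is_marker]))
  if (anyNA(pos) || any(pos < 0)) {
    stop("marker positions must parse as non-negative numbers",
         call. = FALSE)
  }
  map <- tibble::tibble(marker = hdr[is_marker],
                        chromosome = chr_row[is_marker],
                        position_cM = pos, pseudo = FALSE)
  validate_map(map)
  body <- cells[-(1:3)]
  n <- length(body)
  if (n == 0) stop("cross file has no individuals", call. = FALSE)
  mat <- t(vapply(body, pad, character(n_col)))
  ph <- tibble::as_tibble(as.data.frame(mat[, seq_len(n_ph), drop = FALSE],
                                        stringsAsFactors = FALSE))
  names(ph) <- hdr[seq_len(n_ph)]
  for (j in setdiff(names(ph), "id")) ph[[j]] <- as.numeric(ph[[j]])
  codes <- mat[, is_marker, drop = FALSE]
  bad <- !(codes %in% c("A", "H", "B", "-"))
  dim(bad) <- dim(codes)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code %s at row %d, marker %s",
                 codes[bad][1], w[[1]], map$marker[w[[2]]]), call. = FALSE)
  }
  codes[codes == "-"] <- NA_character_
  geno <- char_to_geno(codes)
  rownames(geno) <- ph$id
  colnames(geno) <- map$marker
  structure(list(map = map, geno = geno,
                 pheno = if (ncol(ph) > 1 || names(ph)[1] != "id") ph else
                   ph),
            class = "ril_cross")
}

#' Write / read a scan result as TSV
#'
#' @param scan A `qtl_scan` tibble.
#' @param path File path.
#' @param metadata Named list for the comment header.
#' @export
write_scan_tsv <- function(scan, path, metadata = list()) {
  write_with_meta(scan, path, metadata, delim = "\t")
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           chromosome = readr::col_character()))
  class(out) <- c("qtl_scan", class(out))
  out
}

#' Write / read a fitted multiple-QTL model as JSON
#'
#' Serialises the QTL table with effects, per-QTL LOD, PVE and support
#' intervals, alongside the threshold and metadata.
#'
#' @param model A `qtl_model`.
#' @param path File path.
#' @param metadata Named list merged into the metadata block.
#' @export
write_qtl_model_json <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "qtl_model"))
  obj <- list(
    metadata = c(list(package = "mimpower",
                      version =
                        as.character(utils::packageVersion("mimpower"))),
                 metadata),
    traits = model$traits, n = model$n, threshold = model$threshold,
    qtls = model$qtls
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_qtl_model_json
#' @export
read_qtl_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qtls <- tibble::as_tibble(obj$qtls)
  if (nrow(qtls)) qtls$chromosome <- as.character(qtls$chromosome)
  structure(list(qtls = qtls, traits = obj$traits, n = obj$n,
                 threshold = obj$threshold %||% NA_real_),
            class = "qtl_model")
}
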