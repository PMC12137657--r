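#' Read occurrence records from CSV
#'
#' Expects columns `id`, `longitude`, `latitude`, `year`, `verified`.
#' Rows flagged as unverified are dropped (only expert-verified citizen
#' records enter the analyses), rows with unparseable years are rejected
#' with a message, and coordinates are projected to planar metres about
#' `reference` (defaults to the centroid of the verified records).
#'
#' @param path CSV file path.
#' @param reference optional `(lon0, lat0)`; if `NULL` the centroid of
#'   the retained records is used.
#' @param quiet suppress the drop-count message.
#' @return data frame with columns `id`, `x`, `y`, `year`, `verified`
#'   plus attributes `reference` (projection origin) and `n_dropped`.
#' @export
read_occurrences <- function(path, reference = NULL, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "longitude", "latitude", "year", "verified")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  n0 <- nrow(df)
  year <- suppressWarnings(as.integer(df$year))
  bad_year <- is.na(year)
  verified <- df$verified %in% c(TRUE, "TRUE", "true", "True", 1, "1")
  keep <- verified & !bad_year
  n_dropped <- n0 - sum(keep)
  if (!quiet && n_dropped > 0)
    message(n_dropped, " row(s) dropped (", sum(!verified), " unverified, ",
            sum(bad_year & verified), " bad year)")
  df <- df[keep, , drop = FALSE]
  year <- year[keep]
  occ <- occurrence_records(df$id, df$longitude, df$latitude, year,
                            reference = reference)
  attr(occ, "n_dropped") <- n_dropped
  occ
}

#' Build occurrence records from lon/lat vectors
#'
#' @param id record identifiers.
#' @param lon,lat decimal degrees.
#' @param year integer calendar years, required in \[1900, 2100\].
#' @param reference optional projection origin `(lon0, lat0)`.
#' @return data frame of projected records (`id`, `x`, `y`, `year`,
#'   `verified`), with the projection origin stored as attribute
#'   `reference`.
#' @export
occurrence_records <- function(id, lon, lat, year, reference = NULL) {
  if (length(year) && any(year < 1900 | year > 2100, na.rm = TRUE))
    stop("year outside [1900, 2100]")
  if (is.null(reference)) {
    reference <- if (length(lon)) c(mean(lon), mean(lat)) else c(0, 0)
  }
  xy <- if (length(lon)) project_coordinates(cbind(lon, lat), reference) else
    cbind(x = numeric(0), y = numeric(0))
  out <- data.frame(id = as.character(id), x = xy[, 1], y = xy[, 2],
                    year = as.integer(year),
                    verified = rep(TRUE, length(id)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}

# ---- genotype matrices -----------------------------------------------------

#' Construct a genotype matrix object
#'
#' Diploid biallelic genotypes coded as alternate-allele counts 0/1/2
#' with `NA` for missing, plus an individual-to-locality map.
#'
#' @param calls integer matrix, individuals in rows (rownames = ids),
#'   loci in columns.
#' @param locality_of named vector mapping individual id to locality id.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, locality_of) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate locus ids")
  if (nrow(calls) < 2 || ncol(calls) < 1)
    stop("need at least 2 individuals and 1 locus")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  locality_of <- locality_of[rownames(calls)]
  if (any(is.na(locality_of)))
    stop("individual(s) absent from locality map: ",
         paste(rownames(calls)[is.na(locality_of)], collapse = ", "))
  structure(list(calls = calls, locality_of = locality_of),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x", ncol(x$calls),
      "loci;", length(unique(x$locality_of)), "localities;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read genotypes from VCF or an 012 CSV matrix
#'
#' Both representations of the same cohort produce identical
#' `genotype_matrix` objects. VCF sites that are not biallelic SNPs are
#' skipped with a warning count; `./.` genotypes become `NA`.
#'
#' @param path `.vcf` file or a CSV of 0/1/2 calls (rows = individuals,
#'   first column = individual id).
#' @param locality_of named vector individual -> locality id.
#' @return [genotype_matrix()].
#' @export
read_genotypes <- function(path, locality_of) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    biallelic <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
      !grepl(",", alt)
    n_skip <- sum(!biallelic)
    if (n_skip > 0)
      warning(n_skip, " non-biallelic site(s) skipped")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    ids <- fix[biallelic, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[biallelic, "CHROM"], "_", fix[biallelic, "POS"])[is.na(ids) | ids == "."]
    g <- gsub("\\|", "/", gt)
    cm <- matrix(NA_integer_, nrow(gt), ncol(gt))   # loci x individuals
    cm[g == "0/0"] <- 0L
    cm[g %in% c("0/1", "1/0")] <- 1L
    cm[g == "1/1"] <- 2L
    calls <- t(cm)                                  # individuals x loci
    rownames(calls) <- colnames(gt)
    colnames(calls) <- ids
    genotype_matrix(calls, locality_of)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1]])
    calls <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(calls) <- "integer"
    rownames(calls) <- ids
    genotype_matrix(calls, locality_of)
  }
}

#' Write genotypes as a minimal VCF
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_vcf <- function(G, path) {
  calls <- G$calls
  n_loci <- ncol(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=spreadgen",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (l in seq_len(n_loci)) {
    g <- calls[, l]
    field <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    writeLines(paste(c("1", l, colnames(calls)[l], "A", "T", ".", "PASS",
                       ".", "GT", field), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes as an 012 CSV matrix
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_csv <- function(G, path) {
  df <- data.frame(id = rownames(G$calls), G$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- rasters ---------------------------------------------------------------

#' Construct a raster grid
#'
#' Lower-left origin; `values` stored as an `n_rows x n_cols` matrix with
#' row 1 the TOP row (ESRI ASCII convention shared by all surface
#' modules).
#'
#' @param x_origin,y_origin lower-left corner, metres.
#' @param cell_size cell edge, metres.
#' @param n_rows,n_cols grid dimensions.
#' @param values matrix of cell values (row 1 = top), or a single value
#'   recycled.
#' @param nodata sentinel written for missing cells.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(x_origin, y_origin, cell_size, n_rows, n_cols,
                        values = NA_real_, nodata = -9999) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (length(values) == 1) values <- matrix(values, n_rows, n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(n_rows, n_cols)))
    stop("values must be n_rows x n_cols")
  structure(list(x_origin = x_origin, y_origin = y_origin,
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 values = values, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  invisible(x)
}

#' Cell centre coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @return list with `x` (length `n_cols`) and `y` (length `n_rows`, top
#'   row first), matching the layout of `grid$values`.
#' @export
raster_cell_centres <- function(grid) {
  x <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  y_bottom_up <- grid$y_origin + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(x = x, y = rev(y_bottom_up))
}

#' Write a raster grid as ESRI ASCII
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @export
write_raster <- function(grid, path) {
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$n_cols),
               paste("nrows", grid$n_rows),
               paste("xllcorner", format(grid$x_origin, digits = 15)),
               paste("yllcorner", format(grid$y_origin, digits = 15)),
               paste("cellsize", format(grid$cell_size, digits = 15)),
               paste("NODATA_value", format(grid$nodata, digits = 15))),
             con)
  for (r in seq_len(grid$n_rows))
    writeLines(paste(format(vals[r, ], digits = 17), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' Inverse of [write_raster()]; nodata cells come back as `NA`.
#'
#' @param path file path.
#' @return [raster_grid()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  if (!identical(keys, expected))
    stop("malformed ESRI ASCII header; expected keys: ",
         paste(expected, collapse = ", "))
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  vals <- unname(vals)
  names(vals) <- keys
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  raster_grid(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
              vals[["nrows"]], vals[["ncols"]], m,
              nodata = vals[["nodata_value"]])
}
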