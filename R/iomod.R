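#' Read a genotype matrix from TSV
#'
#' Expects one row per marker with columns `marker`, `chrom`, `pos`
#' (1-based bp) followed by one column per strain holding the allele codes
#' `N2`, `CB` or `NA`. Any other token is treated as a missing call and
#' the total count of such tokens is reported with a message.
#'
#' @param path Path to a tab-separated file (may contain `#` comment lines).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = character(), progress = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(tab))) {
    stop("genotype file must start with columns marker, chrom, pos",
         call. = FALSE)
  }
  if (anyDuplicated(tab$marker)) {
    stop("duplicate marker id: ",
         paste(unique(tab$marker[duplicated(tab$marker)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(tab$chrom, unique(tab$chrom)), tab$pos)
  if (!identical(ord, seq_len(nrow(tab)))) {
    off <- which(ord != seq_len(nrow(tab)))
    stop("marker positions not sorted within chromosome at rows: ",
         paste(utils::head(off, 10), collapse = ", "), call. = FALSE)
  }
  strain_cols <- setdiff(names(tab), need)
  if (!length(strain_cols)) stop("no strain columns found", call. = FALSE)
  codes <- as.matrix(tab[strain_cols])
  al <- matrix(NA_integer_, nrow(codes), ncol(codes),
               dimnames = dimnames(codes))
  al[codes == "N2"] <- 0L
  al[codes == "CB"] <- 1L
  unknown <- sum(!(codes %in% c("N2", "CB", "NA")) & !is.na(codes) &
                   codes != "")
  if (unknown > 0) {
    message(unknown, " unrecognized allele token(s) treated as missing")
  }
  geno_matrix(t(al),
              tibble::tibble(marker = tab$marker, chrom = tab$chrom,
                             pos = tab$pos))
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotypes()]: marker rows, strain columns, codes
#' `N2`/`CB`/`NA`, positions 1-based bp.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @param params Optional named list recorded in the `#` header.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, params = list()) {
  codes <- matrix("NA", nrow(geno$alleles), ncol(geno$alleles))
  codes[geno$alleles == 0L] <- "N2"
  codes[geno$alleles == 1L] <- "CB"
  out <- cbind(geno$markers,
               as.data.frame(t(codes), optional = TRUE) |>
                 stats::setNames(rownames(geno$alleles)))
  .write_tsv_with_header(out, path, params)
}

#' Read a long-format metabolite concentration table
#'
#' Long TSV with columns `sample_id`, `strain`, `batch`, `replicate`,
#' `metabolite`, `class`, `concentration`. An absent `class` column is
#' filled from `class_map`; an absent `replicate` column is numbered
#' within strain by order of appearance. Empty concentration fields
#' become missing values (never zero).
#'
#' @param path Path to a tab-separated file.
#' @param class_map Optional named character vector metabolite -> class
#'   (`"FA"`/`"AA"`), used when the file lacks a `class` column.
#' @return A validated tibble (see [validate_metabolites()]).
#' @export
read_metabolites <- function(path, class_map = NULL) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!"class" %in% names(tab)) {
    if (is.null(class_map)) {
      stop("file has no class column and no class_map was supplied",
           call. = FALSE)
    }
    tab$class <- unname(class_map[tab$metabolite])
    if (anyNA(tab$class)) {
      stop("metabolites absent from class_map: ",
           paste(unique(tab$metabolite[is.na(tab$class)]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!"replicate" %in% names(tab)) {
    key <- paste(tab$strain, tab$sample_id)
    tab$replicate <- stats::ave(seq_along(key), tab$strain, tab$metabolite,
                                FUN = seq_along)
  }
  tab$concentration <- as.numeric(tab$concentration)
  validate_metabolites(tab)
  tibble::as_tibble(tab)[.metab_cols]
}

#' Write a long-format metabolite table to TSV
#' @param tab Metabolite table (see [validate_metabolites()]).
#' @param path Output path.
#' @param params Optional named list recorded in the `#` header.
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(tab, path, params = list()) {
  validate_metabolites(tab)
  .write_tsv_with_header(tab, path, params)
}

#' Read an introgression-line panel from TSV
#'
#' Columns: `strain`, `background`, `chrom`, `start`, `end` with 1-based
#' inclusive coordinates in the file; internally coordinates are half-open
#' `[start, end)` 0-based, so `start` is decremented by one on read.
#'
#' @param path Path to a tab-separated file.
#' @return A validated tibble (see [validate_il_panel()]).
#' @export
read_il_panel <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tab$start <- tab$start - 1
  validate_il_panel(tab)
  tibble::as_tibble(tab)
}

#' Write an introgression-line panel to TSV
#' @param panel IL panel tibble (internal half-open coordinates).
#' @param path Output path.
#' @param params Optional named list recorded in the `#` header.
#' @return `path`, invisibly.
#' @export
write_il_panel <- function(panel, path, params = list()) {
  validate_il_panel(panel)
  out <- panel
  out$start <- out$start + 1
  .write_tsv_with_header(out, path, params)
}

#' Write a result table to TSV with a provenance header
#'
#' All result tables (scan results, power tables, heritability tables,
#' ...) are written as plain TSV preceded by `#`-prefixed header lines
#' recording the package version, the seed and any parameters supplied,
#' plus the coordinate convention.
#'
#' @param result A data frame.
#' @param path Output path.
#' @param params Named list of parameters (e.g. `list(seed = 1, q = 0.05)`).
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path, params = list()) {
  .write_tsv_with_header(as.data.frame(result), path, params)
}

#' Read back a result table written by [write_table()]
#' @param path Path to the TSV.
#' @return A tibble (header comments dropped).
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

.write_tsv_with_header <- function(df, path, params = list()) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open ", path,
                                           " for writing", call. = FALSE))
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("metaboqtl"))
  writeLines(c(
    paste0("# metaboqtl version: ", ver),
    "# coordinates: files 1-based inclusive; bp",
    if (length(params)) {
      paste0("# ", names(params), ": ",
             vapply(params, function(p) paste(format(p), collapse = ","),
                    character(1)))
    }
  ), con)
  # full precision so numeric round-trips are exact
  df2 <- df
  num <- vapply(df2, is.numeric, logical(1))
  df2[num] <- lapply(df2[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  utils::write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
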