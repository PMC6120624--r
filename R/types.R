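#' Construct a genotype matrix
#'
#' Container for biallelic RIL (or IL) genotypes from a two-parent cross.
#' Alleles are coded `0` for the N2 parental allele, `1` for the CB4856
#' (CB) allele and `NA` for missing calls. Markers are kept in strict
#' (chromosome, position) order.
#'
#' @param alleles Integer matrix, strains x markers, values in `{0, 1, NA}`.
#'   Row names are strain identifiers; column names marker identifiers.
#' @param markers Data frame with columns `marker`, `chrom`, `pos` (bp),
#'   one row per column of `alleles`, in the same order.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `alleles` and `markers`.
#' @export
geno_matrix <- function(alleles, markers) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(markers)))
  if (ncol(alleles) != nrow(markers)) {
    stop("`alleles` has ", ncol(alleles), " columns but `markers` has ",
         nrow(markers), " rows", call. = FALSE)
  }
  if (anyDuplicated(markers$marker)) {
    stop("duplicate marker id: ",
         paste(unique(markers$marker[duplicated(markers$marker)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(alleles))) {
    stop("`alleles` must have strain row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(alleles))) {
    stop("duplicate strain ids", call. = FALSE)
  }
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("allele codes must be 0 (N2), 1 (CB) or NA", call. = FALSE)
  # markers must be sorted within the given chromosome order
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    off <- which(ord != seq_len(nrow(markers)))
    stop("markers not ordered by (chromosome, position); first offending rows: ",
         paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
  }
  colnames(alleles) <- markers$marker
  structure(list(alleles = alleles, markers = markers), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$alleles), " strains x ", ncol(x$alleles),
      " markers on ", length(unique(x$markers$chrom)), " chromosomes\n",
      sep = "")
  cat("  missing calls: ", sum(is.na(x$alleles)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$alleles)

#' Strain identifiers of a genotype matrix
#' @param x A `geno_matrix`.
#' @return Character vector of strain ids.
#' @export
strains <- function(x) rownames(x$alleles)

# Internal: required columns of the long metabolite table.
.metab_cols <- c("sample_id", "strain", "batch", "replicate",
                 "metabolite", "class", "concentration")

#' Validate a long-format metabolite concentration table
#'
#' Checks the invariants of the raw concentration table: one row per
#' (sample, metabolite), a single class per metabolite, and non-negative
#' concentrations where present. Used by the readers and by
#' [simulate_traits()]; exported so user-assembled tables can be checked.
#'
#' @param tab Data frame with columns `sample_id`, `strain`, `batch`,
#'   `replicate`, `metabolite`, `class` (one of `"FA"`, `"AA"`),
#'   `concentration` (nmol/mg protein, `NA` for missing).
#' @return The table, invisibly, as a tibble.
#' @export
validate_metabolites <- function(tab) {
  tab <- tibble::as_tibble(tab)
  miss <- setdiff(.metab_cols, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dup <- duplicated(tab[c("sample_id", "metabolite")])
  if (any(dup)) {
    stop("duplicated (sample_id, metabolite): ",
         paste(utils::head(paste(tab$sample_id[dup], tab$metabolite[dup]), 3),
               collapse = "; "), call. = FALSE)
  }
  if (any(tab$concentration < 0, na.rm = TRUE)) {
    stop("negative concentrations present", call. = FALSE)
  }
  ncl <- tapply(tab$class, tab$metabolite, function(z) length(unique(z)))
  if (any(ncl > 1)) {
    stop("metabolites with inconsistent class: ",
         paste(names(ncl)[ncl > 1], collapse = ", "), call. = FALSE)
  }
  if (!all(tab$class %in% c("FA", "AA"))) {
    stop("class must be \"FA\" or \"AA\"", call. = FALSE)
  }
  invisible(tab)
}

#' Construct a per-strain trait table
#'
#' Matrix container for the mapping phenotype: per-strain mean z-scores,
#' one column per metabolite, with the replicate count behind each mean.
#'
#' @param mean Numeric matrix, strains x metabolites (`NA` allowed).
#' @param n Integer matrix of replicate counts, same dimensions.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(mean, n) {
  stopifnot(identical(dim(mean), dim(n)),
            identical(dimnames(mean), dimnames(n)))
  if (any(n[!is.na(mean)] < 1)) stop("replicate count < 1 under a value",
                                     call. = FALSE)
  structure(list(mean = mean, n = n), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("<trait_table> ", nrow(x$mean), " strains x ", ncol(x$mean),
      " metabolites; ", sum(is.na(x$mean)), " missing cells\n", sep = "")
  invisible(x)
}

#' Validate an introgression-line panel description
#'
#' One row per introgressed segment: `strain`, `background` (`"N2"` or
#' `"CB"`), `chrom`, `start`, `end`. Coordinates are half-open
#' `[start, end)` in bp (the TSV reader converts from 1-based inclusive).
#' Segments of one strain must not overlap.
#'
#' @param panel Data frame as above.
#' @return The panel, invisibly, as a tibble.
#' @export
validate_il_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  need <- c("strain", "background", "chrom", "start", "end")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(panel$background %in% c("N2", "CB"))) {
    stop("background must be \"N2\" or \"CB\"", call. = FALSE)
  }
  if (any(panel$start >= panel$end)) stop("empty or inverted interval",
                                          call. = FALSE)
  by_sc <- split(panel, paste(panel$strain, panel$chrom))
  for (g in by_sc) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    if (any(g$start[-1] < g$end[-nrow(g)])) {
      stop("overlapping introgressions for strain ", g$strain[1],
           " on ", g$chrom[1], call. = FALSE)
    }
  }
  invisible(panel)
}
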