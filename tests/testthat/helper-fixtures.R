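# Shared fixtures, built in code at test time.

# A small 2-chromosome marker map with regular spacing.
tiny_map <- function(n_per_chrom = 10, spacing = 1e6,
                     chroms = c("I", "II")) {
  dplyr::bind_rows(lapply(chroms, function(ch) {
    tibble::tibble(chrom = ch, pos = spacing * seq_len(n_per_chrom))
  })) |>
    dplyr::mutate(marker = sprintf("M%04d", dplyr::row_number()),
                  .before = 1)
}

# A long metabolite table assembled by hand: `conc` is a named list
# metabolite -> per-sample concentrations; samples define strain/batch.
make_metab <- function(conc, strain = NULL, batch = 1L, class = "FA") {
  n <- length(conc[[1]])
  if (is.null(strain)) strain <- sprintf("ST%02d", seq_len(n))
  if (length(batch) == 1) batch <- rep(batch, n)
  if (length(class) == 1) class <- rep(class, length(conc))
  dplyr::bind_rows(lapply(seq_along(conc), function(i) {
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)),
                   strain = strain, batch = batch,
                   replicate = stats::ave(seq_len(n), strain,
                                          FUN = seq_along),
                   metabolite = names(conc)[i], class = class[i],
                   concentration = conc[[i]])
  }))
}

# Direct trait-vector scan convenience: named y over a geno_matrix.
scan_vector <- function(y, geno, name = "trait") {
  single_marker_scan(matrix(y, dimnames = list(names(y), name)), geno)
}
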