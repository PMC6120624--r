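#' Default marker map for a simulated RIL panel
#'
#' Six chromosomes (I, II, III, IV, V, X) with physical lengths matching
#' the C. elegans genome and markers evenly spaced, allocated to
#' chromosomes proportionally to length. The default total of 729
#' markers matches the density of a typical RIL genetic map for this
#' cross.
#'
#' @param n_markers Total number of markers (default 729).
#' @return Tibble with columns `marker`, `chrom`, `pos` (bp).
#' @export
default_marker_map <- function(n_markers = 729) {
  chrom_len <- c(I = 15.1e6, II = 15.3e6, III = 13.8e6,
                 IV = 17.5e6, V = 20.9e6, X = 17.7e6)
  n_per <- round(n_markers * chrom_len / sum(chrom_len))
  # fix rounding so counts total n_markers
  while (sum(n_per) != n_markers) {
    i <- if (sum(n_per) < n_markers) which.max(chrom_len / n_per) else
      which.min(chrom_len / n_per)
    n_per[i] <- n_per[i] + sign(n_markers - sum(n_per))
  }
  dplyr::bind_rows(lapply(names(chrom_len), function(ch) {
    n <- n_per[[ch]]
    tibble::tibble(chrom = ch,
                   pos = round(seq(0.1e6, chrom_len[[ch]] - 0.1e6,
                                   length.out = n)))
  })) |>
    dplyr::mutate(marker = sprintf("M%04d", dplyr::row_number()),
                  .before = 1)
}

#' Replicate design of a replicated RIL metabolomics experiment
#'
#' Emulates the replication structure of the study design this package
#' targets: each parental strain measured `parent_reps` times, a
#' replicated subset of RILs measured several times, and the remaining
#' RILs once. The default mirrors a 199-RIL panel in which 7 RILs were
#' measured 5x, 44 RILs 4x, 27 RILs 2x and 121 RILs once, with parents
#' at n = 7; the 51 strains with n >= 3 form the heritability subset.
#'
#' @param strain_ids Character vector of RIL ids (length 199 by default).
#' @param parent_reps Replicates per parental strain.
#' @return Named integer vector of replicate counts including `N2`, `CB`.
#' @export
ril_study_design <- function(strain_ids = sprintf("RIL%03d", 1:199),
                             parent_reps = 7L) {
  n <- length(strain_ids)
  counts <- rep(1L, n)
  sizes <- c(5L, 4L, 2L)
  groups <- c(7L, 44L, 27L)
  # scale the replicated groups down proportionally for smaller panels
  if (n < sum(groups) + 1L) groups <- pmax(1L, round(groups * n / 199))
  idx <- 1L
  for (g in seq_along(groups)) {
    take <- min(groups[g], n - idx + 1L)
    if (take <= 0) break
    counts[idx:(idx + take - 1L)] <- sizes[g]
    idx <- idx + take
  }
  stats::setNames(c(rep(parent_reps, 2L), counts),
                  c("N2", "CB", strain_ids))
}

#' Simulate RIL genotypes over a marker map
#'
#' Each strain's chromosome is an independent two-state Markov chain: the
#' first marker's parental origin is Bernoulli(0.5) and each subsequent
#' marker flips origin with probability `switch_prob` (no interference;
#' independent across chromosomes and strains). This reproduces the
#' block-mosaic LD structure of a selfed two-parent RIL panel.
#'
#' @param n_strains Number of RILs.
#' @param marker_map Tibble with `chrom`, `pos` (and optionally `marker`),
#'   e.g. [default_marker_map()].
#' @param switch_prob Per-adjacent-marker recombination probability in
#'   `[0, 0.5]`.
#' @param seed Integer RNG seed.
#' @param strain_ids Optional strain names (default `RIL001`, ...).
#' @return A [geno_matrix()].
#' @export
simulate_ril_genotypes <- function(n_strains, marker_map = default_marker_map(),
                                   switch_prob = 0.03, seed = 1,
                                   strain_ids = sprintf("RIL%03d",
                                                        seq_len(n_strains))) {
  if (switch_prob < 0 || switch_prob > 0.5) {
    stop("switch_prob must be in [0, 0.5]", call. = FALSE)
  }
  marker_map <- tibble::as_tibble(marker_map)
  if (!"marker" %in% names(marker_map)) {
    marker_map$marker <- sprintf("M%04d", seq_len(nrow(marker_map)))
  }
  tab <- table(marker_map$chrom)
  if (any(tab < 2)) stop("need >= 2 markers per chromosome", call. = FALSE)
  set.seed(seed)
  chroms <- unique(marker_map$chrom)
  blocks <- lapply(chroms, function(ch) {
    m <- sum(marker_map$chrom == ch)
    first <- stats::rbinom(n_strains, 1L, 0.5)
    flips <- matrix(stats::rbinom(n_strains * (m - 1L), 1L, switch_prob),
                    nrow = n_strains)
    states <- cbind(first, flips)
    # cumulative flips mod 2 along each chromosome
    t(apply(states, 1L, cumsum)) %% 2L
  })
  alleles <- do.call(cbind, blocks)
  rownames(alleles) <- strain_ids
  geno_matrix(alleles, marker_map[c("marker", "chrom", "pos")])
}

#' Simulate an introgression-line panel
#'
#' Every IL carries the background parent's allele at all markers except
#' those falling inside its introgressed segment(s), which carry the other
#' parent's allele. Segments use half-open `[start, end)` bp coordinates.
#'
#' @param background `"N2"` or `"CB"`: the recipient genetic background.
#' @param segments Tibble with `strain`, `chrom`, `start`, `end`; one row
#'   per introgressed segment.
#' @param marker_map Tibble with `marker`, `chrom`, `pos`.
#' @return List with elements `geno` (a [geno_matrix()]) and `panel`
#'   (validated IL panel tibble with the `background` column filled in).
#' @export
simulate_il_panel <- function(background = c("N2", "CB"), segments,
                              marker_map = default_marker_map()) {
  background <- match.arg(background)
  segments <- tibble::as_tibble(segments)
  marker_map <- tibble::as_tibble(marker_map)
  if (!"marker" %in% names(marker_map)) {
    marker_map$marker <- sprintf("M%04d", seq_len(nrow(marker_map)))
  }
  bg_code <- if (background == "N2") 0L else 1L
  strains <- unique(segments$strain)
  alleles <- matrix(bg_code, nrow = length(strains), ncol = nrow(marker_map),
                    dimnames = list(strains, marker_map$marker))
  pos0 <- marker_map$pos - 1  # 0-based marker coordinate
  for (i in seq_len(nrow(segments))) {
    hit <- marker_map$chrom == segments$chrom[i] &
      pos0 >= segments$start[i] & pos0 < segments$end[i]
    if (!any(hit)) {
      stop("segment ", segments$chrom[i], ":[", segments$start[i], ",",
           segments$end[i], ") of strain ", segments$strain[i],
           " covers no marker", call. = FALSE)
    }
    alleles[segments$strain[i], hit] <- 1L - bg_code
  }
  panel <- segments
  panel$background <- background
  validate_il_panel(panel)
  list(geno = geno_matrix(alleles, marker_map[c("marker", "chrom", "pos")]),
       panel = panel[c("strain", "background", "chrom", "start", "end")])
}

#' Allele-effect difference implied by a variance fraction
#'
#' Under balanced allele frequencies a QTL whose two genotype-group means
#' differ by `a` explains a fraction `R2 = (a^2/4) / (a^2/4 + sigma^2)` of
#' the trait variance, so `a = 2 * sigma * sqrt(R2 / (1 - R2))`. At
#' `R2 = 0.5`, `sigma = 1` this gives the anchor `a = 2`.
#'
#' @param r2 Variance fraction in `(0, 1)`.
#' @param noise_sd Residual standard deviation.
#' @return The group-mean difference `a` in trait units.
#' @export
additive_effect <- function(r2, noise_sd = 1) {
  stopifnot(all(r2 > 0), all(r2 < 1))
  2 * noise_sd * sqrt(r2 / (1 - r2))
}

#' Specify planted QTL for trait simulation
#'
#' @param metabolite Metabolite name the effect acts on.
#' @param marker Marker id or index of the (first) locus.
#' @param r2 Variance fraction the effect should explain, in `(0, 1)`.
#' @param direction `"+"` if the CB allele raises the trait, `"-"` if it
#'   lowers it.
#' @param marker2 Second locus for an epistatic (product-coded) effect;
#'   `NA` for a purely additive QTL.
#' @return Tibble with one row per effect; rows from several calls can be
#'   combined with [dplyr::bind_rows()].
#' @export
qtl_spec <- function(metabolite, marker, r2, direction = "+", marker2 = NA) {
  spec <- tibble::tibble(metabolite = metabolite, marker = marker,
                         marker2 = marker2, r2 = r2, direction = direction)
  stopifnot(all(spec$r2 > 0), all(spec$r2 < 1),
            all(spec$direction %in% c("+", "-")))
  tot <- tapply(spec$r2, spec$metabolite, sum)
  if (any(tot >= 1)) {
    stop("total planted variance fraction >= 1 for: ",
         paste(names(tot)[tot >= 1], collapse = ", "), call. = FALSE)
  }
  spec
}

#' Specify batch structure for trait simulation
#'
#' The default emulates a growth design in which every strain's first
#' replicate is grown in one of the first `n_batches - 1` time-separated
#' batches (round-robin over strains) and all later replicates of the
#' replicated subset in a final extra batch (`assign = "study"`).
#' `assign = "round_robin"` spreads all samples over all batches instead.
#'
#' @param n_batches Number of batches (default 6: five primary plus the
#'   replication batch).
#' @param offsets Additive per-batch offsets in trait units: a numeric
#'   vector of length `n_batches` applied to every metabolite, or a
#'   `n_batches` x metabolite matrix.
#' @param assign `"study"` or `"round_robin"` (see above).
#' @return A list of class `batch_spec`.
#' @export
batch_spec <- function(n_batches = 6L, offsets = rep(0, n_batches),
                       assign = c("study", "round_robin")) {
  assign <- match.arg(assign)
  if (is.matrix(offsets)) {
    stopifnot(nrow(offsets) == n_batches)
  } else {
    stopifnot(length(offsets) == n_batches)
  }
  stopifnot(all(is.finite(offsets)))
  structure(list(n_batches = as.integer(n_batches), offsets = offsets,
                 assign = assign), class = "batch_spec")
}

.batch_of <- function(spec, strain_index, replicate) {
  if (spec$assign == "round_robin") {
    ((strain_index + replicate - 2L) %% spec$n_batches) + 1L
  } else {
    ifelse(replicate == 1L,
           ((strain_index - 1L) %% max(1L, spec$n_batches - 1L)) + 1L,
           spec$n_batches)
  }
}

.offset_of <- function(spec, batch, metabolite, metabolites) {
  if (is.matrix(spec$offsets)) {
    spec$offsets[cbind(batch, match(metabolite, metabolites))]
  } else {
    spec$offsets[batch]
  }
}

#' Simulate a metabolite concentration table with planted QTL
#'
#' Builds per-sample "concentrations" as
#' `baseline + genetic value + batch offset + N(0, noise_sd^2)`.
#' Additive QTL contribute `+/- a/2` per allele with
#' `a = additive_effect(r2, noise_sd)`; epistatic effects use centred
#' product coding `u1 * u2 / 2` with `u = 2 * allele - 1`, scaled by the
#' same variance-fraction algebra so the interaction explains its stated
#' fraction. Metabolites named in `qtl` carry their effects; extra
#' metabolites listed in `metabolites` are pure noise.
#'
#' @param genotypes A [geno_matrix()]; may include parental rows (`N2`
#'   all-0, `CB` all-1, see [add_parents()]).
#' @param qtl A [qtl_spec()] tibble, or `NULL` for no genetic effects.
#' @param batches A [batch_spec()], or `NULL` for a single batch with no
#'   offset.
#' @param replicates Named integer vector of replicate counts per strain
#'   (e.g. [ril_study_design()]); strains absent from the vector get 1.
#' @param noise_sd Residual standard deviation (trait units).
#' @param seed Integer RNG seed.
#' @param metabolites Metabolite names to emit (default: those in `qtl`).
#' @param classes Named character vector metabolite -> class; defaults to
#'   `"FA"` for all.
#' @param baseline Positive baseline added so concentrations stay >= 0.
#' @return A validated long metabolite table (see
#'   [validate_metabolites()]).
#' @export
simulate_traits <- function(genotypes, qtl = NULL, batches = NULL,
                            replicates = NULL, noise_sd = 1, seed = 1,
                            metabolites = NULL, classes = NULL,
                            baseline = 10) {
  stopifnot(noise_sd > 0)
  if (is.null(batches)) batches <- batch_spec(1L, 0)
  ids <- strains(genotypes)
  reps <- rep(1L, length(ids))
  names(reps) <- ids
  if (!is.null(replicates)) {
    known <- intersect(names(replicates), ids)
    reps[known] <- as.integer(replicates[known])
  }
  if (is.null(metabolites)) {
    metabolites <- if (is.null(qtl)) "met_1" else unique(qtl$metabolite)
  }
  if (is.null(classes)) {
    classes <- stats::setNames(rep("FA", length(metabolites)), metabolites)
  }
  mk_idx <- function(m) {
    if (is.numeric(m)) return(as.integer(m))
    i <- match(m, genotypes$markers$marker)
    if (anyNA(i)) stop("unknown marker: ", paste(m[is.na(i)], collapse = ", "),
                       call. = FALSE)
    i
  }
  # per-strain genetic value for each metabolite
  G <- matrix(0, length(ids), length(metabolites),
              dimnames = list(ids, metabolites))
  if (!is.null(qtl) && nrow(qtl)) {
    tot <- tapply(qtl$r2, qtl$metabolite, sum)
    if (any(tot >= 1)) stop("planted variance fractions sum to >= 1",
                            call. = FALSE)
    for (i in seq_len(nrow(qtl))) {
      a <- additive_effect(qtl$r2[i], noise_sd) *
        (if (qtl$direction[i] == "+") 1 else -1)
      j1 <- mk_idx(qtl$marker[i])
      x1 <- genotypes$alleles[, j1]
      term <- if (is.na(qtl$marker2[i])) {
        a * (x1 - 0.5)
      } else {
        j2 <- mk_idx(qtl$marker2[i])
        x2 <- genotypes$alleles[, j2]
        a * (2 * x1 - 1) * (2 * x2 - 1) / 2
      }
      G[, qtl$metabolite[i]] <- G[, qtl$metabolite[i]] + term
    }
  }
  set.seed(seed)
  rows <- lapply(seq_along(ids), function(s) {
    r <- seq_len(reps[s])
    tibble::tibble(strain = ids[s], replicate = rep(r, each = 1),
                   batch = .batch_of(batches, s, r))
  })
  design <- dplyr::bind_rows(rows)
  design$sample_id <- sprintf("S%04d", seq_len(nrow(design)))
  long <- tidyr::expand_grid(design, metabolite = metabolites)
  long$class <- unname(classes[long$metabolite])
  g <- G[cbind(long$strain, long$metabolite)]
  off <- .offset_of(batches, long$batch, long$metabolite, metabolites)
  long$concentration <- baseline + g + off +
    stats::rnorm(nrow(long), 0, noise_sd)
  if (any(long$concentration < 0, na.rm = TRUE)) {
    warning("clamped ", sum(long$concentration < 0),
            " simulated concentrations at 0; raise `baseline` to avoid")
    long$concentration <- pmax(long$concentration, 0)
  }
  out <- long[.metab_cols]
  validate_metabolites(out)
  out
}

#' Append parental genotype rows to a RIL genotype matrix
#'
#' Adds a pure `N2` row (all 0) and a pure `CB` row (all 1) so parental
#' strains can be simulated alongside the RILs.
#'
#' @param geno A [geno_matrix()].
#' @return A [geno_matrix()] with two extra strains `N2` and `CB`.
#' @export
add_parents <- function(geno) {
  m <- ncol(geno$alleles)
  extra <- rbind(N2 = rep(0L, m), CB = rep(1L, m))
  geno_matrix(rbind(geno$alleles, extra), geno$markers)
}
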