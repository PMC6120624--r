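#' Directional introgression-line confirmation test
#'
#' Compares each introgression line (IL) to its genetic-background
#' parent with a one-sided equal-variance Student's t-test in the
#' direction hypothesized from the RIL mapping (e.g. an IL carrying a
#' trait-raising introgressed allele is tested for *higher* values than
#' the background parent). P-values are Benjamini-Hochberg adjusted
#' across the ILs tested together; an IL confirms the QTL when its
#' adjusted q-value is below `alpha_q` and the observed shift matches
#' the tested direction.
#'
#' @param il_values Long tibble with `strain`, `value`: IL replicate
#'   trait values (typically 4 replicates per IL).
#' @param background_values Numeric vector of replicate values of the
#'   background parent.
#' @param directions Named character vector IL strain -> `"higher"` or
#'   `"lower"` (the tested direction relative to the background).
#' @param alpha_q Confirmation level on the BH q-value (default 0.05).
#' @return Tibble per IL: `strain`, `direction`, `shift` (IL mean minus
#'   background mean), `t`, `p` (one-sided), `q`, `confirms`.
#' @export
il_confirmation_test <- function(il_values, background_values, directions,
                                 alpha_q = 0.05) {
  ils <- unique(il_values$strain)
  miss <- setdiff(ils, names(directions))
  if (length(miss)) stop("no tested direction for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(directions %in% c("higher", "lower")))
  bg <- background_values[!is.na(background_values)]
  res <- lapply(ils, function(s) {
    v <- il_values$value[il_values$strain == s]
    v <- v[!is.na(v)]
    dir <- directions[[s]]
    if (length(v) < 3 || length(bg) < 3) {
      stop("need >= 3 replicates per group (IL ", s, ")", call. = FALSE)
    }
    if (stats::sd(v) == 0 && stats::sd(bg) == 0) {
      return(tibble::tibble(strain = s, direction = dir,
                            shift = mean(v) - mean(bg), t = NA_real_,
                            p = NA_real_))
    }
    tt <- stats::t.test(v, bg, var.equal = TRUE,
                        alternative = if (dir == "higher") "greater"
                        else "less")
    tibble::tibble(strain = s, direction = dir,
                   shift = mean(v) - mean(bg),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  res <- dplyr::bind_rows(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  obs_dir <- ifelse(res$shift > 0, "higher", "lower")
  res$confirms <- !is.na(res$q) & res$q < alpha_q &
    obs_dir == res$direction
  res
}

# --- minimal interval set algebra on (start, end) half-open pairs -------

.iv_norm <- function(iv) {
  # iv: data.frame/tibble with start, end; merge overlaps, sort
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[i])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

.iv_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, c("start", "end"), drop = FALSE])
  res <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e) res[[length(res) + 1]] <- data.frame(start = s, end = e)
  }
  if (!length(res)) return(a[0, c("start", "end"), drop = FALSE])
  .iv_norm(do.call(rbind, res))
}

.iv_subtract <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  b <- .iv_norm(b)
  for (j in seq_len(nrow(b))) {
    res <- list()
    for (i in seq_len(nrow(a))) {
      s <- a$start[i]; e <- a$end[i]
      bs <- b$start[j]; be <- b$end[j]
      if (be <= s || bs >= e) {
        res[[length(res) + 1]] <- data.frame(start = s, end = e)
      } else {
        if (bs > s) res[[length(res) + 1]] <- data.frame(start = s, end = bs)
        if (be < e) res[[length(res) + 1]] <- data.frame(start = be, end = e)
      }
    }
    a <- if (length(res)) do.call(rbind, res) else
      data.frame(start = numeric(), end = numeric())
  }
  a
}

#' Narrow a QTL region from IL confirmation results
#'
#' The narrowed region is the intersection, over all confirming ILs, of
#' their introgressed intervals on the QTL chromosome, minus the union
#' of the non-confirming ILs' introgressed intervals: a confirming IL
#' must carry the causal allele inside its introgression, while a
#' non-confirming IL's introgression localizes where the effect is
#' absent. If the subtraction splits the region, all fragments are
#' returned with a warning.
#'
#' @param panel Validated IL panel tibble (half-open bp intervals).
#' @param results Tibble from [il_confirmation_test()] with `strain` and
#'   `confirms`.
#' @param qtl_chrom Chromosome of the QTL.
#' @return Tibble with `chrom`, `start`, `end` (half-open bp), one row
#'   per fragment.
#' @export
narrow_region <- function(panel, results, qtl_chrom) {
  validate_il_panel(panel)
  on_chrom <- panel[panel$chrom == qtl_chrom, , drop = FALSE]
  conf <- results$strain[results$confirms]
  nonconf <- results$strain[!results$confirms]
  conf <- intersect(conf, on_chrom$strain)
  if (!length(conf)) {
    stop("no confirming IL has an introgression on ", qtl_chrom,
         call. = FALSE)
  }
  region <- NULL
  for (s in conf) {
    iv <- .iv_norm(on_chrom[on_chrom$strain == s, c("start", "end")])
    region <- if (is.null(region)) iv else .iv_intersect(region, iv)
    if (!nrow(region)) {
      stop("confirming ILs have no common introgressed interval on ",
           qtl_chrom, " (conflict at ", s, ")", call. = FALSE)
    }
  }
  sub <- on_chrom[on_chrom$strain %in% nonconf, c("start", "end")]
  if (nrow(sub)) region <- .iv_subtract(region, sub)
  if (!nrow(region)) {
    stop("non-confirming introgression(s) of ",
         paste(intersect(nonconf, on_chrom$strain), collapse = ", "),
         " cover the entire region supported by ",
         paste(conf, collapse = ", "), call. = FALSE)
  }
  if (nrow(region) > 1) {
    warning("narrowed region split into ", nrow(region), " fragments")
  }
  tibble::tibble(chrom = qtl_chrom, start = region$start, end = region$end)
}

#' Prioritize candidate genes in a QTL region
#'
#' Filters a user-supplied gene table to genes overlapping the narrowed
#' region and ranks them: polymorphism class first (1 = high-impact
#' coding, 2 = regulatory, 3 = low-impact coding), then functional tag
#' (`lipid-metabolism` and `transcription-factor` before `other`), then
#' genomic position for a stable order. Genes lacking positions are
#' excluded and counted.
#'
#' @param genes Tibble with `gene`, `chrom`, `start`, `end` (half-open
#'   bp), `class` (1/2/3 or the labels `"high-impact coding"`,
#'   `"regulatory"`, `"low-impact coding"`), `tag` (`"lipid-metabolism"`,
#'   `"transcription-factor"` or `"other"`).
#' @param region Tibble with `chrom`, `start`, `end` (one row per
#'   fragment), e.g. from [narrow_region()].
#' @return The overlapping genes, ranked, with a `rank` column.
#' @export
prioritize_candidates <- function(genes, region) {
  genes <- tibble::as_tibble(genes)
  no_pos <- is.na(genes$start) | is.na(genes$end) | is.na(genes$chrom)
  if (any(no_pos)) {
    message("excluding ", sum(no_pos), " gene(s) without positions")
    genes <- genes[!no_pos, , drop = FALSE]
  }
  cls <- genes$class
  if (!is.numeric(cls)) {
    cls <- match(cls, c("high-impact coding", "regulatory",
                        "low-impact coding"))
    if (anyNA(cls)) stop("unknown polymorphism class label", call. = FALSE)
  }
  stopifnot(all(cls %in% 1:3))
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(region))) {
    hit <- hit | (genes$chrom == region$chrom[i] &
                    genes$start < region$end[i] &
                    genes$end > region$start[i])
  }
  out <- genes[hit, , drop = FALSE]
  if (!nrow(out)) return(dplyr::mutate(out, rank = integer(0)))
  cls <- cls[hit]
  tag_rank <- ifelse(out$tag %in% c("lipid-metabolism",
                                    "transcription-factor"), 1L, 2L)
  ord <- order(cls, tag_rank, out$chrom, out$start, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
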