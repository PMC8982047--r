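#' Window scheme for identity-by-state lengths
#'
#' The region to one side of the focal allele is divided into `M` half-open
#' windows `(prev, next]` by `M - 1` increasing bp offsets from the focal
#' site; the final window `(last boundary, Inf)` also receives pairs with no
#' difference within the available flank.
#'
#' @param boundaries increasing bp offsets (default five 50-kb windows with
#'   an open-ended sixth).
#' @export
window_scheme <- function(boundaries = c(50e3, 100e3, 150e3, 200e3, 250e3)) {
  stopifnot(length(boundaries) >= 1, all(diff(boundaries) > 0),
            all(boundaries > 0))
  structure(list(boundaries = as.numeric(boundaries),
                 M = length(boundaries) + 1L),
            class = "window_scheme")
}

#' Bin an IBS length into a window
#'
#' Half-open `(lo, hi]` assignment: a length exactly at a boundary belongs
#' to the lower window.  Lengths beyond the last boundary, and the `Inf`
#' sentinel for "no difference within the flank", map to the final window.
#'
#' @param length bp length(s), `Inf` allowed.
#' @param scheme a [window_scheme()].
#' @return integer window index (1-based).
#' @export
bin_length <- function(length, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  # number of boundaries strictly below the length gives the (lo, hi] window
  idx <- findInterval(length, scheme$boundaries, left.open = TRUE)
  as.integer(pmin(idx + 1L, scheme$M))
}

#' Pairwise identity-by-state length around a focal allele
#'
#' The bp distance from the focal site to the nearest position, in the
#' stated direction, where two haplotypes differ; `Inf` when no difference
#' exists within the available flank.  Sites where either haplotype has a
#' missing genotype are skipped as non-informative.
#'
#' @param hap_a,hap_b 0/1 genotype vectors over shared `positions` (both
#'   carrying the derived focal allele).
#' @param positions bp coordinates of the genotyped sites.
#' @param focal_pos bp coordinate of the focal site.
#' @param direction `"down"` (increasing coordinates) or `"up"`.
#' @export
pairwise_ibs_length <- function(hap_a, hap_b, positions, focal_pos,
                                direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(length(hap_a) == length(positions),
            length(hap_b) == length(positions))
  ok <- !is.na(hap_a) & !is.na(hap_b)
  diffpos <- positions[ok & (hap_a != hap_b)]
  d <- if (direction == "down") diffpos - focal_pos else focal_pos - diffpos
  d <- d[d > 0]
  if (length(d) == 0) Inf else min(d)
}

#' Collect binned IBS records across loci
#'
#' For each locus, all pairwise comparisons among the derived-carrying
#' haplotypes are taken in each requested direction.  With
#' `mask_singletons`, sites carried by exactly one of the derived-allele
#' haplotypes at that locus are removed before the length computation
#' (masking variants most exposed to genotyping error; removing sites can
#' only push the first difference outward).
#'
#' @param loci list of haplotype sets (see [simulate_haplotypes()]), each
#'   with `positions`, `genotypes` (rows = haplotypes; the derived carriers
#'   are rows where `derived` is `TRUE`, all rows by default), `focal_pos`,
#'   and optionally per-locus `u` and `r`.
#' @param scheme a [window_scheme()].
#' @param directions subset of `c("down", "up")`.
#' @param mask_singletons remove per-locus singleton sites first.
#' @return an `ibs_data` data frame with columns `locus_id`, `direction`,
#'   `pair`, `length_bp`, `window`, plus per-locus attributes `n_derived`,
#'   `locus_r`, `locus_u`.
#' @export
collect_ibs <- function(loci, scheme, directions = c("down", "up"),
                        mask_singletons = FALSE) {
  stopifnot(inherits(scheme, "window_scheme"), length(directions) >= 1)
  directions <- match.arg(directions, c("down", "up"), several.ok = TRUE)
  out <- list()
  n_derived <- integer(0)
  locus_r <- numeric(0)
  locus_u <- numeric(0)
  for (li in seq_along(loci)) {
    hs <- loci[[li]]
    gt <- hs$genotypes
    der <- if (!is.null(hs$derived)) which(hs$derived) else seq_len(nrow(gt))
    if (length(der) < 2) {
      warning(sprintf("locus %d skipped: fewer than 2 derived haplotypes", li))
      next
    }
    gt <- gt[der, , drop = FALSE]
    pos <- hs$positions
    if (mask_singletons && ncol(gt) > 0) {
      cnt <- colSums(gt == 1, na.rm = TRUE)
      keep <- cnt != 1
      gt <- gt[, keep, drop = FALSE]
      pos <- pos[keep]
    }
    n <- nrow(gt)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
    for (dir in directions) {
      len <- apply(pairs, 1, function(pr)
        pairwise_ibs_length(gt[pr[1], ], gt[pr[2], ], pos, hs$focal_pos, dir))
      out[[length(out) + 1]] <- data.frame(
        locus_id = li, direction = dir,
        pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
        length_bp = len, window = bin_length(len, scheme))
    }
    n_derived[as.character(li)] <- n
    locus_r[as.character(li)] <- if (!is.null(hs$r)) hs$r else NA_real_
    locus_u[as.character(li)] <- if (!is.null(hs$u)) hs$u else NA_real_
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = integer(0), direction = character(0),
               pair = character(0), length_bp = numeric(0), window = integer(0))
  structure(res, n_derived = n_derived, locus_r = locus_r, locus_u = locus_u,
            scheme = scheme, class = c("ibs_data", "data.frame"))
}

#' Total record-count identity
#'
#' The number of IBS records is exactly
#' `directions * sum(choose(n_locus, 2))` over loci; with a shared `n` this
#' is `directions * A * choose(n, 2)`.
#'
#' @param A number of loci (or vector of per-locus `n` when `n` is missing).
#' @param n derived haplotypes per locus.
#' @param directions 1 or 2.
#' @export
ibs_record_count <- function(A, n = NULL, directions = 2) {
  if (is.null(n)) return(directions * sum(choose(A, 2)))
  directions * A * choose(n, 2)
}

#' Window counts from IBS records
#'
#' @param data an `ibs_data` data frame (or any data frame with a `window`
#'   column), or a named list of per-locus window-count matrices.
#' @param scheme a [window_scheme()].
#' @param by_locus return a matrix of per-locus counts instead of the pooled
#'   vector.
#' @export
ibs_window_counts <- function(data, scheme, by_locus = FALSE) {
  M <- scheme$M
  if (by_locus) {
    tab <- table(factor(data$locus_id), factor(data$window, levels = seq_len(M)))
    return(matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab)))
  }
  as.numeric(table(factor(data$window, levels = seq_len(M))))
}

#' Simulate binned IBS data for a set of conditioned trajectories
#'
#' The fast data-generation path: for each conditioned trajectory one
#' haplotype set of `n` derived carriers is simulated (focal allele at the
#' midpoint when both directions are used) and every pair is assigned its
#' first-difference window per direction.
#'
#' @param trajectories a conditioned `trajectory_set`.
#' @param locus a [locus_params()].
#' @param n derived haplotypes per locus.
#' @param scheme a [window_scheme()].
#' @param directions 1 (downstream of the focal allele) or 2 (both sides).
#' @param seed integer seed or `NULL`.
#' @return an `ibs_data` data frame (window indices only; individual bp
#'   lengths are not retained on this path).
#' @export
simulate_ibs_data <- function(trajectories, locus, n, scheme, directions = 2,
                              seed = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(scheme, "window_scheme"), directions %in% c(1, 2))
  .hd_set_seed(seed)
  bp <- .demog_bp(trajectories$demography)
  pw <- cpp_ibs_pair_windows(trajectories$counts, bp$sizes,
                             pmin(bp$ends, .Machine$double.xmax),
                             as.integer(n), locus$u, locus$r,
                             scheme$boundaries, as.integer(directions),
                             .coal_time_cap(trajectories$demography))
  npair <- choose(n, 2)
  dirnames <- c("down", "up")[seq_len(directions)]
  rows <- lapply(seq_along(pw), function(a) {
    data.frame(locus_id = a,
               direction = rep(dirnames, each = npair),
               pair = rep(seq_len(npair), directions),
               length_bp = NA_real_,
               window = as.integer(pw[[a]]))
  })
  res <- do.call(rbind, rows)
  nd <- setNames(rep(as.integer(n), length(pw)), as.character(seq_along(pw)))
  structure(res,
            n_derived = nd,
            locus_r = setNames(rep(locus$r, length(pw)), names(nd)),
            locus_u = setNames(rep(locus$u, length(pw)), names(nd)),
            scheme = scheme, class = c("ibs_data", "data.frame"))
}

#' Write / read IBS records as TSV
#' @param data an `ibs_data` data frame.
#' @param path file path.
#' @export
write_ibs <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_derived: %s", paste(attr(data, "n_derived"), collapse = ",")),
    sprintf("# locus_r: %s", paste(attr(data, "locus_r"), collapse = ",")),
    sprintf("# locus_u: %s", paste(attr(data, "locus_u"), collapse = ",")),
    sprintf("# boundaries: %s",
            paste(attr(data, "scheme")$boundaries, collapse = ","))), con)
  write.table(data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibs
#' @export
read_ibs <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^# ", key, ": "), "", ln[1]), ",")[[1]]
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  scheme <- window_scheme(as.numeric(get("boundaries")))
  ids <- as.character(sort(unique(tab$locus_id)))
  structure(tab,
            n_derived = setNames(as.integer(get("n_derived")), ids),
            locus_r = setNames(as.numeric(get("locus_r")), ids),
            locus_u = setNames(as.numeric(get("locus_u")), ids),
            scheme = scheme, class = c("ibs_data", "data.frame"))
}
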