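#' Write haplotypes in ms-style text
#'
#' A `segsites:` line, a `positions:` line (fractions of the region length),
#' and one 0/1 row per haplotype.
#'
#' @param hapset a `haplotype_set`.
#' @param path output file.
#' @export
write_ms <- function(hapset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  gt <- hapset$genotypes
  writeLines("//", con)
  writeLines(sprintf("segsites: %d", ncol(gt)), con)
  writeLines(paste("positions:",
                   paste(sprintf("%.6f", hapset$positions / hapset$l),
                         collapse = " ")), con)
  apply(gt, 1, function(row) writeLines(paste(row, collapse = ""), con))
  invisible(path)
}

# one VCF body chunk for a locus; haplotype columns already ordered by
# individual (2 per column)
.vcf_locus_rows <- function(chrom, positions, gt, focal_pos, focal_gt) {
  pos <- as.integer(positions) + 1L  # 1-based coordinates
  keep <- !duplicated(pos)
  pos <- pos[keep]
  gt <- gt[, keep, drop = FALSE]
  ord <- order(c(pos, as.integer(focal_pos) + 1L))
  allpos <- c(pos, as.integer(focal_pos) + 1L)[ord]
  allgt <- cbind(gt, focal_gt)[, ord, drop = FALSE]
  id <- ifelse(allpos == as.integer(focal_pos) + 1L, "focal", ".")
  nind <- nrow(allgt) / 2
  gtcol <- vapply(seq_len(ncol(allgt)), function(j) {
    paste(paste(allgt[seq(1, 2 * nind, 2), j],
                allgt[seq(2, 2 * nind, 2), j], sep = "|"),
          collapse = "\t")
  }, character(1))
  sprintf("%s\t%d\t%s\tA\tT\t.\tPASS\t.\tGT\t%s", chrom, allpos, id, gtcol)
}

#' Generate a fully synthetic phased cohort fixture
#'
#' For each of `A` loci a conditioned allele-frequency trajectory is drawn
#' (selection coefficient fixed, or drawn per locus from a gamma DFE over
#' deleterious 4Ns magnitudes), `n` derived-carrying and `S - n`
#' ancestral-class haplotypes are simulated with the focal allele at the
#' region midpoint, and the cohort is written as a phased VCF together with
#' a focal-variant table and a truth JSON recording the generating
#' parameters per locus.
#'
#' @param demography a [demographic_model()].
#' @param selection a [selection_params()] / 4Ns value, or
#'   `list(shape =, scale =)` for a gamma DFE.
#' @param sample a [sample_config()]; `S` haplotypes are emitted
#'   (`S` must be even and at most 128).
#' @param locus a [locus_params()] (focal position at the midpoint).
#' @param A number of loci.
#' @param dir output directory.
#' @param seed integer seed or `NULL`.
#' @param keep_haplotypes also return the in-memory haplotype sets (for
#'   round-trip checks against [ingest_cohort()]).
#' @return invisible list of file paths (`vcf`, `focal_table`, `truth`) and,
#'   if requested, `loci`.
#' @export
generate_fixture <- function(demography, selection, sample, locus, A, dir,
                             seed = NULL, keep_haplotypes = FALSE) {
  stopifnot(sample$S %% 2 == 0, sample$S <= 128, sample$n <= sample$S)
  .hd_set_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_dfe <- is.list(selection) && !inherits(selection, "selection_params") &&
    !is.null(selection$shape)
  body <- character(0)
  focal_rows <- list()
  truth <- list()
  contigs <- character(0)
  kept <- list()
  for (a in seq_len(A)) {
    gamma_a <- if (is_dfe) -rgamma(1, shape = selection$shape,
                                   scale = selection$scale) else
      .as_selection(selection)$gamma
    ts <- sample_trajectories_at_frequency(demography,
                                           selection_params(gamma_a), sample,
                                           n_target = 1)
    hs <- simulate_haplotypes(ts$counts[[1]], demography, locus,
                              n = sample$n, n_ancestral = sample$S - sample$n)
    chrom <- sprintf("chrL%d", a)
    contigs[a] <- sprintf("##contig=<ID=%s,length=%d>", chrom,
                          as.integer(locus$l))
    if (keep_haplotypes) kept[[a]] <- hs
    shuffle <- sample(sample$S)
    gt <- hs$genotypes[shuffle, , drop = FALSE]
    focal_gt <- as.integer(hs$derived)[shuffle]
    body <- c(body, .vcf_locus_rows(chrom, hs$positions, gt,
                                    locus$focal_pos, focal_gt))
    focal_rows[[a]] <- data.frame(
      chrom = chrom, pos = as.integer(locus$focal_pos) + 1L, ref = "A",
      alt = "T", derived_allele = "T", derived_count = sample$n,
      mean_r_up = locus$r, mean_r_down = locus$r, u = locus$u)
    truth[[a]] <- list(locus = chrom, gamma = gamma_a,
                       final_sample_count = ts$final_sample_count[1],
                       age = length(ts$counts[[1]]))
  }
  vcf_path <- file.path(dir, "cohort.vcf")
  ft_path <- file.path(dir, "focal_variants.tsv")
  truth_path <- file.path(dir, "truth.json")
  nind <- sample$S / 2
  header <- c("##fileformat=VCFv4.2",
              "##source=haplodfe-fixture",
              contigs,
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sprintf("ind%03d", seq_len(nind))),
                    collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  ft_empty <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         derived_allele = character(0),
                         derived_count = integer(0), mean_r_up = numeric(0),
                         mean_r_down = numeric(0), u = numeric(0))
  write.table(if (A > 0) do.call(rbind, focal_rows) else ft_empty, ft_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(model = demography$label,
                            dfe = if (is_dfe) selection else NULL,
                            gamma = if (!is_dfe) .as_selection(selection)$gamma
                            else NULL,
                            loci = truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, focal_table = ft_path, truth = truth_path,
                 loci = if (keep_haplotypes) kept))
}

#' Ingest a phased cohort: VCF plus focal-variant table
#'
#' Extracts the derived-carrying haplotypes around every focal variant,
#' verifies phasing and flank lengths, and computes both-direction IBS
#' records.  Loci with insufficient flank (closer than the last window
#' boundary to a contig end) are excluded with a warning.
#'
#' @param vcf_path phased VCF file.
#' @param focal_table path to a TSV with columns `chrom`, `pos` (1-based),
#'   `derived_allele`, `mean_r_up`, `mean_r_down`, `u`, or a data frame.
#' @param scheme a [window_scheme()].
#' @param mask_singletons passed to [collect_ibs()].
#' @return an `ibs_data` data frame.
#' @export
ingest_cohort <- function(vcf_path, focal_table, scheme,
                          mask_singletons = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("ingest_cohort requires the vcfR package")
  ft <- if (is.data.frame(focal_table)) focal_table else
    read.table(focal_table, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  # an allele column of all "T"/"F" would otherwise parse as logical
  if (is.logical(ft$derived_allele))
    ft$derived_allele <- ifelse(ft$derived_allele, "T", "F")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  contig_len <- local({
    meta <- vcf@meta
    ln <- grep("^##contig=", meta, value = TRUE)
    ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
    setNames(lens, ids)
  })
  flank <- max(scheme$boundaries)
  loci <- list()
  for (i in seq_len(nrow(ft))) {
    chrom <- as.character(ft$chrom[i])
    fpos <- as.numeric(ft$pos[i])
    clen <- contig_len[chrom]
    # 1-based coordinates: left flank = fpos - 1, right flank = clen - fpos
    if (!is.na(clen) && (fpos - 1 < flank - 1 || clen - fpos < flank - 1)) {
      warning(sprintf("locus %s:%g excluded: flank shorter than %g bp",
                      chrom, fpos, flank))
      next
    }
    sel_row <- which(fix[, "CHROM"] == chrom & as.numeric(fix[, "POS"]) == fpos)
    if (length(sel_row) != 1)
      stop(sprintf("focal variant %s:%g absent from the VCF", chrom, fpos))
    on_chrom <- which(fix[, "CHROM"] == chrom)
    gsub_rows <- gt_raw[on_chrom, , drop = FALSE]
    if (any(grepl("/", gsub_rows, fixed = TRUE)))
      stop(sprintf("unphased genotypes on contig %s", chrom))
    # haplotype matrix: 2 columns per individual
    hap <- do.call(cbind, lapply(seq_len(ncol(gsub_rows)), function(j) {
      parts <- strsplit(gsub_rows[, j], "|", fixed = TRUE)
      matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2,
             byrow = TRUE)
    }))
    pos <- as.numeric(fix[on_chrom, "POS"])
    frow <- match(sel_row, on_chrom)
    der_allele <- as.character(ft$derived_allele[i])
    alt <- unname(as.character(fix[sel_row, "ALT"]))
    der_code <- if (identical(der_allele, alt)) 1L else 0L
    carriers <- which(hap[frow, ] == der_code)
    if (length(carriers) < 2) {
      warning(sprintf("locus %s:%g skipped: fewer than 2 derived haplotypes",
                      chrom, fpos))
      next
    }
    keep <- pos != fpos
    loci[[length(loci) + 1]] <- list(
      positions = pos[keep],
      genotypes = t(hap[keep, carriers, drop = FALSE]),
      derived = rep(TRUE, length(carriers)),
      focal_pos = fpos,
      r = mean(c(ft$mean_r_up[i], ft$mean_r_down[i])),
      u = ft$u[i])
  }
  collect_ibs(loci, scheme, directions = c("down", "up"),
              mask_singletons = mask_singletons)
}

#' Read and validate a YAML run configuration
#'
#' The configuration names the demography, sampling setup, locus rates,
#' window scheme, 4Ns grid, Monte-Carlo budgets and seeds used by the
#' command-line interface; every downstream precondition checkable from the
#' configuration is validated before any simulation starts.
#'
#' @param path YAML file.
#' @return list with constructed `demography`, `sample`, `locus`, `scheme`,
#'   `grid`, `budgets`, `ess_threshold`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dem <- demographic_model(
    sizes = vapply(cfg$demography$epochs, function(e) e$size, numeric(1)),
    durations = vapply(cfg$demography$epochs, function(e)
      if (is.null(e$duration)) Inf else e$duration, numeric(1)),
    label = if (!is.null(cfg$demography$label)) cfg$demography$label else "model")
  samp <- sample_config(S = cfg$sample$S, f = cfg$sample$f,
                        tolerance = if (is.null(cfg$sample$tolerance)) 0 else
                          cfg$sample$tolerance,
                        n = if (is.null(cfg$sample$n))
                          round(cfg$sample$f * cfg$sample$S) else cfg$sample$n,
                        A = if (is.null(cfg$sample$A)) 1 else cfg$sample$A)
  loc <- do.call(locus_params, cfg$locus[intersect(names(cfg$locus),
                                                   c("u", "r", "l", "focal_pos"))])
  sch <- if (is.null(cfg$windows)) window_scheme() else
    window_scheme(as.numeric(cfg$windows$boundaries))
  grid <- if (is.null(cfg$grid)) seq(-200, 200, by = 5) else
    seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
  list(demography = dem, sample = samp, locus = loc, scheme = sch,
       grid = grid,
       budgets = list(K = if (is.null(cfg$budgets$K)) 2000 else cfg$budgets$K,
                      reps = if (is.null(cfg$budgets$reps)) 20 else
                        cfg$budgets$reps),
       ess_threshold = if (is.null(cfg$ess_threshold)) 100 else
         cfg$ess_threshold,
       seed = cfg$seed)
}
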