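#' Scan a set of gene alignments for selection signatures
#'
#' Runs, per gene: the branch-model LRT with the focal species as
#' foreground (quickly evolving genes, QEG), the branch-model LRT with the
#' highland species set as foreground (common QEG, CQEG), the branch-site
#' LRT with the focal species as foreground plus naive empirical Bayes site
#' posteriors (positively selected genes, PSG), and the lineage-specific /
#' convergent substitution screens. Benjamini-Hochberg correction is
#' applied across genes to the branch-site p-values (unconverged fits are
#' excluded from the family by default). Genes with fewer than `min_taxa`
#' taxa are skipped with a logged reason; an alignment taxon missing from
#' the tree is a fatal error.
#'
#' Every step is deterministic, so results do not depend on gene order and
#' re-runs reproduce outputs byte for byte.
#'
#' @param alignments directory containing per-gene FASTA files, a character
#'   vector of FASTA paths, or a list of [codon_alignment()]s.
#' @param tree species tree (`ape::phylo`, or a newick path).
#' @param focal focal species for QEG/PSG tests and the lineage-specific
#'   screen.
#' @param plateau character vector of highland species (foreground of the
#'   CQEG test); `NULL` skips that stage.
#' @param partner second species of the convergent screen (default: the
#'   first plateau species other than `focal`).
#' @param tests subset of
#'   `c("branch_focal", "branch_plateau", "branch_site", "screens")`.
#' @param alpha_qeg raw-p threshold for QEG/CQEG calls (default 0.01).
#' @param alpha_psg corrected-p threshold for PSG calls (default 0.05).
#' @param posterior_threshold site posterior cutoff (default 0.95).
#' @param correction multiple-testing correction for the branch-site
#'   family: `"BH"`, `"bonferroni"` or `"none"`.
#' @param include_unconverged include unconverged branch-site fits in the
#'   correction family (default `FALSE`; they are reported either way).
#' @param min_taxa minimum taxa per gene (default 3).
#' @param freq codon frequency model.
#' @param min_background_identity background conservation required by the
#'   screens (default 1 = strict).
#' @param out_dir optional directory for TSV outputs (`gene_scan.tsv`,
#'   `substitution_calls.tsv`, `category_counts.tsv`, `qeg.txt`, ... and
#'   `scan_log.txt`).
#' @param control optimizer control passed to the fitting functions.
#' @param code a [genetic_code()].
#' @return a `selection_scan`: list with `records` (per-gene data.frame),
#'   `calls` (substitution calls), `categories` (from
#'   [classify_categories()]), and `log`.
#' @export
run_scan <- function(alignments, tree, focal, plateau = NULL, partner = NULL,
                     tests = c("branch_focal", "branch_plateau",
                               "branch_site", "screens"),
                     alpha_qeg = 0.01, alpha_psg = 0.05,
                     posterior_threshold = 0.95,
                     correction = c("BH", "bonferroni", "none"),
                     include_unconverged = FALSE, min_taxa = 3L,
                     freq = "F3x4", min_background_identity = 1,
                     out_dir = NULL, control = list(),
                     code = genetic_code()) {
  correction <- match.arg(correction)
  tests <- match.arg(tests, several.ok = TRUE)
  if (is.character(tree)) tree <- read_species_tree(tree)
  alns <- load_alignments(alignments, code)
  if (is.null(partner) && !is.null(plateau))
    partner <- setdiff(plateau, focal)[1L]
  if (is.null(plateau)) tests <- setdiff(tests, "branch_plateau")
  log <- character(0)
  records <- list()
  calls <- list()
  for (aln in alns) {
    g <- aln$gene_id
    if (length(aln$taxa) < min_taxa) {
      log <- c(log, sprintf("SKIP %s: only %d taxa (< %d)", g,
                            length(aln$taxa), min_taxa))
      next
    }
    miss <- setdiff(aln$taxa, tree$tip.label)
    if (length(miss) > 0L)
      stop("gene ", g, ": taxa not in tree: ", paste(miss, collapse = ", "))
    rec <- scan_one_gene(aln, tree, focal, plateau, partner, tests, freq,
                         posterior_threshold, min_background_identity,
                         control, code)
    records[[g]] <- rec$record
    if (!is.null(rec$calls) && nrow(rec$calls) > 0L)
      calls[[g]] <- rec$calls
    log <- c(log, sprintf("OK %s", g))
  }
  if (length(records) == 0L) {
    warning("no genes scanned")
    empty <- list(records = NULL, calls = NULL,
                  categories = classify_categories(NULL), log = log)
    class(empty) <- "selection_scan"
    if (!is.null(out_dir)) write_scan(empty, out_dir)
    return(empty)
  }
  rec <- do.call(rbind, records[order(names(records))])
  rownames(rec) <- NULL
  if ("branch_site" %in% tests) {
    fam <- if (include_unconverged) rep(TRUE, nrow(rec)) else rec$bs_converged
    fam[is.na(fam)] <- FALSE
    rec$q_psg <- NA_real_
    if (any(fam))
      rec$q_psg[fam] <- stats::p.adjust(rec$p_psg[fam],
        method = c(BH = "BH", bonferroni = "bonferroni", none = "none")[correction])
  }
  calls <- if (length(calls) > 0L) do.call(rbind, calls[order(names(calls))])
    else .calls_frame()
  rownames(calls) <- NULL
  cats <- classify_categories(rec, alpha_qeg = alpha_qeg,
                              alpha_psg = alpha_psg)
  out <- structure(list(records = rec, calls = calls, categories = cats,
                        log = log), class = "selection_scan")
  if (!is.null(out_dir)) write_scan(out, out_dir)
  out
}

load_alignments <- function(alignments, code) {
  if (is.character(alignments)) {
    paths <- if (length(alignments) == 1L && dir.exists(alignments))
      sort(list.files(alignments, pattern = "\\.(fa|fasta|fna)$",
                      full.names = TRUE))
    else alignments
    alignments <- lapply(paths, read_codon_alignment, code = code)
  }
  if (!all(vapply(alignments, inherits, logical(1), "codon_alignment")))
    stop("alignments must be codon_alignment objects or FASTA paths")
  alignments
}

scan_one_gene <- function(aln, tree, focal, plateau, partner, tests, freq,
                          posterior_threshold, min_background_identity,
                          control, code) {
  pi <- codon_frequencies(aln, freq, code)
  rec <- data.frame(gene_id = aln$gene_id, n_taxa = length(aln$taxa),
                    n_codons = aln$n_codons, stringsAsFactors = FALSE)
  null_fit <- fit_branch_model(aln, tree, "one_ratio", pi = pi,
                               control = control, code = code)
  rec$lnL0 <- null_fit$lnL
  rec$omega <- unname(null_fit$omega[1L])
  rec$kappa <- null_fit$kappa
  rec$converged <- null_fit$convergence == 0L
  if ("branch_focal" %in% tests) {
    alt <- fit_branch_model(aln, mark_foreground(tree, focal), "two_ratio",
                            pi = pi, null_fit = null_fit, control = control,
                            code = code)
    lrt <- likelihood_ratio_test(null_fit, alt, df = 1L)
    rec$lnL_focal <- alt$lnL
    rec$omega_bg_focal <- unname(alt$omega["omega_bg"])
    rec$omega_fg_focal <- unname(alt$omega["omega_fg"])
    rec$p_qeg <- lrt$p_value
    rec$focal_converged <- alt$convergence == 0L
  }
  if ("branch_plateau" %in% tests) {
    alt <- fit_branch_model(aln, mark_foreground(tree, plateau), "two_ratio",
                            pi = pi, null_fit = null_fit, control = control,
                            code = code)
    lrt <- likelihood_ratio_test(null_fit, alt, df = 1L)
    rec$lnL_plateau <- alt$lnL
    rec$omega_bg_plateau <- unname(alt$omega["omega_bg"])
    rec$omega_fg_plateau <- unname(alt$omega["omega_fg"])
    rec$p_cqeg <- lrt$p_value
    rec$plateau_converged <- alt$convergence == 0L
  }
  if ("branch_site" %in% tests) {
    trf <- mark_foreground(tree, focal)
    bs0 <- fit_branch_site_model(aln, trf, alternative = FALSE, pi = pi,
                                 null_fit = null_fit, control = control,
                                 code = code)
    bs1 <- fit_branch_site_model(aln, trf, alternative = TRUE, pi = pi,
                                 null_fit = null_fit, control = control,
                                 code = code)
    lrt <- likelihood_ratio_test(bs0, bs1, df = 1L)
    post <- site_posteriors(bs1, threshold = posterior_threshold)
    rec$lnL_bs_null <- bs0$lnL
    rec$lnL_bs_alt <- bs1$lnL
    rec$omega2 <- unname(bs1$omega["omega2"])
    rec$p_psg <- lrt$p_value
    rec$n_flagged <- sum(post$flagged)
    rec$bs_converged <- bs0$convergence == 0L && bs1$convergence == 0L
  }
  gene_calls <- NULL
  if ("screens" %in% tests) {
    ls <- find_lineage_specific_substitutions(
      aln, focal, min_background_identity = min_background_identity,
      code = code)
    gene_calls <- ls
    if (!is.null(partner) && !is.na(partner)) {
      cv <- find_convergent_substitutions(
        aln, c(focal, partner),
        min_background_identity = min_background_identity, code = code)
      gene_calls <- rbind(ls, cv)
    }
    rec$n_lineage_specific <- sum(gene_calls$kind == "lineage_specific")
    rec$n_convergent <- sum(gene_calls$kind == "convergent")
  }
  list(record = rec, calls = gene_calls)
}

#' Classify scanned genes into QEG/CQEG/PSG/LSM categories
#'
#' Category rules: QEG and CQEG require a raw branch-model p below
#' `alpha_qeg` (default 0.01, uncorrected); PSG requires a corrected
#' branch-site p below `alpha_psg` (default 0.05) AND at least one site
#' with selection posterior above the threshold used in the scan; LSM is
#' the subset of PSGs that also carry at least one lineage-specific
#' replacement.
#'
#' @param records per-gene data.frame from [run_scan()] (`NULL` gives empty
#'   categories).
#' @param alpha_qeg,alpha_psg thresholds as above.
#' @return list with `sets` (named list of gene-id vectors QEG, CQEG, PSG,
#'   LSM), `membership` (logical matrix gene x category), and `counts`
#'   (data.frame of category and intersection sizes, Venn-style).
#' @export
classify_categories <- function(records, alpha_qeg = 0.01,
                                alpha_psg = 0.05) {
  cats <- c("QEG", "CQEG", "PSG", "LSM")
  if (is.null(records) || nrow(records) == 0L) {
    m <- matrix(logical(0), 0L, 4L, dimnames = list(NULL, cats))
    return(list(sets = setNames(rep(list(character(0)), 4L), cats),
                membership = m,
                counts = data.frame(category = cats, n = 0L)))
  }
  g <- records$gene_id
  col <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  qeg <- !is.na(col("p_qeg")) & col("p_qeg") < alpha_qeg
  cqeg <- !is.na(col("p_cqeg")) & col("p_cqeg") < alpha_qeg
  psg <- !is.na(col("q_psg")) & col("q_psg") < alpha_psg &
    !is.na(col("n_flagged")) & col("n_flagged") >= 1L
  lsm <- psg & !is.na(col("n_lineage_specific")) &
    col("n_lineage_specific") >= 1L
  membership <- cbind(QEG = qeg, CQEG = cqeg, PSG = psg, LSM = lsm)
  rownames(membership) <- g
  sets <- lapply(cats, function(cc) g[membership[, cc]])
  names(sets) <- cats
  pairs <- utils::combn(cats, 2L)
  counts <- rbind(
    data.frame(category = cats, n = colSums(membership)),
    data.frame(category = apply(pairs, 2L, paste, collapse = "&"),
               n = apply(pairs, 2L, function(p)
                 sum(membership[, p[1L]] & membership[, p[2L]]))))
  rownames(counts) <- NULL
  list(sets = sets, membership = membership, counts = counts)
}

#' @export
print.selection_scan <- function(x, ...) {
  n <- if (is.null(x$records)) 0L else nrow(x$records)
  cat("selection_scan over", n, "genes\n")
  if (n > 0L) {
    cn <- x$categories$counts
    cat(paste(sprintf("  %s: %d", cn$category[1:4], cn$n[1:4]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

write_scan <- function(scan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scan$records)) wt(scan$records, "gene_scan.tsv")
  if (!is.null(scan$calls)) wt(scan$calls, "substitution_calls.tsv")
  wt(scan$categories$counts, "category_counts.tsv")
  for (cc in names(scan$categories$sets))
    writeLines(scan$categories$sets[[cc]],
               file.path(out_dir, paste0(tolower(cc), ".txt")))
  writeLines(scan$log, file.path(out_dir, "scan_log.txt"))
  invisible(out_dir)
}
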