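#' Default codon frequencies for simulation
#'
#' F3x4-style frequencies built from a fixed, mildly GC-rich positional
#' base composition typical of vertebrate coding sequence, so simulated
#' alignments have realistic unequal codon usage.
#'
#' @param code a [genetic_code()].
#' @return frequency vector over the 61 sense codons.
#' @export
default_codon_pi <- function(code = genetic_code()) {
  base <- rbind(A = c(0.27, 0.30, 0.22),
                C = c(0.22, 0.23, 0.28),
                G = c(0.30, 0.20, 0.27),
                T = c(0.21, 0.27, 0.23))
  scm <- matrix(unlist(strsplit(code$sense_codons, "")), ncol = 3L,
                byrow = TRUE)
  pi <- base[scm[, 1L], 1L] * base[scm[, 2L], 2L] * base[scm[, 3L], 3L]
  pi <- pi / sum(pi)
  setNames(as.numeric(pi), code$sense_codons)
}

#' The default simulation tree
#'
#' A fixed 8-taxon tree with two non-sister foreground leaves (`C` and `E`),
#' mimicking a non-monophyletic set of highland lineages on a lowland
#' background; branch lengths in expected substitutions per codon site.
#'
#' @return a marked `ape::phylo` (foreground `C`, `E`).
#' @export
default_study_tree <- function() {
  tr <- read_species_tree(text = paste0(
    "((A:0.10,(B:0.08,C:0.12):0.05):0.07,",
    "((D:0.09,E:0.11):0.06,(F:0.10,G:0.10):0.04):0.05,H:0.15);"))
  mark_foreground(tr, c("C", "E"))
}

## sample child states for one branch given parent states and P (rows = from)
evolve_states <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    i <- which(states == s)
    out[i] <- sample.int(ncol(P), length(i), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a codon alignment on a tree
#'
#' Root codons are drawn from `pi`; each branch evolves states with the
#' branch's transition matrix at its length, under exactly the same GY94
#' machinery the likelihood engine uses. Regimes:
#' \describe{
#'   \item{null}{`list(type = "null", omega)` — one omega everywhere.}
#'   \item{branch}{`list(type = "branch", omega_bg, omega_fg)` — marked
#'     foreground branches evolve with `omega_fg`.}
#'   \item{branch_site}{`list(type = "branch_site", p0, p1, omega0, omega2)`
#'     — per-column site class (0, 1, 2a, 2b) drawn i.i.d. from the Model A
#'     proportions and held constant across the tree; foreground branches
#'     use `omega2` in classes 2a/2b.}
#' }
#' A column that would carry an (unobservable) internal stop cannot occur:
#' stops are not in the state space. Deterministic given `seed`.
#'
#' @param tree a marked `ape::phylo` (marks required for branch/branch-site
#'   regimes).
#' @param n_codons number of codon columns.
#' @param regime regime list (see above); default neutral `omega = 1`.
#' @param kappa transition/transversion ratio (default 2).
#' @param pi codon frequencies (default [default_codon_pi()]).
#' @param gene_id gene identifier.
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @param code a [genetic_code()].
#' @return a [codon_alignment()]; for branch-site regimes the drawn class
#'   per column is stored in `attr(, "site_class")`.
#' @export
simulate_codon_alignment <- function(tree, n_codons,
                                     regime = list(type = "null", omega = 1),
                                     kappa = 2, pi = default_codon_pi(),
                                     gene_id = "gene", seed = NULL,
                                     code = genetic_code()) {
  if (!is.null(seed)) set.seed(seed)
  po <- stats::reorder(tree, "postorder")
  fg_po <- {
    fg <- foreground_edges(tree)
    ord <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                 paste(tree$edge[, 1L], tree$edge[, 2L]))
    fg[ord]
  }
  ntip <- length(po$tip.label)
  nnode <- po$Nnode
  ## omega per edge per class (columns = classes)
  site_class <- NULL
  if (regime$type == "null") {
    om <- matrix(regime$omega, nrow = nrow(po$edge), ncol = 1L)
    site_class <- rep(1L, n_codons)
  } else if (regime$type == "branch") {
    if (!any(fg_po)) stop("branch regime requires foreground marks")
    om <- matrix(ifelse(fg_po, regime$omega_fg, regime$omega_bg), ncol = 1L)
    site_class <- rep(1L, n_codons)
  } else if (regime$type == "branch_site") {
    if (!any(fg_po)) stop("branch_site regime requires foreground marks")
    s <- regime$p0 + regime$p1
    props <- modelA_props(s, regime$p0 / s)
    om <- cbind(c0 = ifelse(fg_po, regime$omega0, regime$omega0),
                c1 = 1,
                c2a = ifelse(fg_po, regime$omega2, regime$omega0),
                c2b = ifelse(fg_po, regime$omega2, 1))
    site_class <- sample.int(4L, n_codons, replace = TRUE, prob = props)
  } else stop("unknown regime type: ", regime$type)
  ## eigensystems for the distinct omegas; mixture classes share the
  ## synonymous rate: all class generators divided by one constant chosen
  ## so the mixture-average background rate is 1 (same convention as the
  ## branch-site likelihood, whose unit is then absorbed by the per-gene
  ## rate scale it estimates)
  rc <- NULL
  if (regime$type == "branch_site") {
    bg_om <- c(regime$omega0, 1, regime$omega0, 1)
    rc <- sum(props * vapply(bg_om, function(wv)
      raw_rate_constant(kappa, wv, pi, code), numeric(1)))
  }
  uom <- sort(unique(as.vector(om)))
  eigs <- lapply(uom, function(w)
    rate_matrix_eigen(build_rate_matrix(kappa, w, pi, code,
                                        rate_constant = rc), pi))
  names(eigs) <- as.character(uom)
  states <- matrix(NA_integer_, nrow = ntip + nnode, ncol = n_codons)
  root <- ntip + 1L
  states[root, ] <- sample.int(length(pi), n_codons, replace = TRUE, prob = pi)
  for (k in rev(seq_len(nrow(po$edge)))) {     # preorder traversal
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    t_e <- po$edge.length[k]
    for (cl in sort(unique(site_class))) {
      cols <- which(site_class == cl)
      if (length(cols) == 0L) next
      P <- transition_probabilities(eigs[[as.character(om[k, cl])]], t_e)
      states[ch, cols] <- evolve_states(states[par, cols], P)
    }
  }
  sc <- code$sense_codons
  seqs <- vapply(seq_len(ntip), function(i)
    paste(sc[states[i, ]], collapse = ""), character(1))
  names(seqs) <- po$tip.label
  aln <- codon_alignment(seqs[tree$tip.label], gene_id = gene_id, code = code)
  if (regime$type == "branch_site")
    attr(aln, "site_class") <- c("c0", "c1", "c2a", "c2b")[site_class]
  aln
}

## canonical (lexicographically first) sense codon for a residue
codon_for_residue <- function(res, code = genetic_code()) {
  hit <- code$sense_codons[code$aa[code$sense_codons] == res]
  if (length(hit) == 0L) stop("residue '", res, "' is not encodable")
  hit[1L]
}

#' Plant a lineage-specific or convergent replacement into an alignment
#'
#' Overwrites one codon column: focal taxa receive the canonical codon of
#' the target residue, all other taxa the canonical codon of the background
#' residue, making the column an unambiguous planted event for the screens.
#'
#' @param aln a [codon_alignment()].
#' @param column 1-based codon column.
#' @param kind `"lineage_specific"` (one focal taxon) or `"convergent"`
#'   (two focal taxa).
#' @param focal character vector of focal taxa (length 1 or 2 per `kind`).
#' @param background_res,focal_res one-letter residues, distinct.
#' @param code a [genetic_code()].
#' @return the modified alignment; planted events accumulate in
#'   `attr(, "planted")` (data.frame gene_id, kind, focal, column,
#'   background_res, focal_res).
#' @export
plant_substitution <- function(aln, column, kind, focal, background_res,
                               focal_res, code = genetic_code()) {
  stopifnot(column >= 1L, column <= aln$n_codons,
            background_res != focal_res)
  kind <- match.arg(kind, c("lineage_specific", "convergent"))
  if (kind == "lineage_specific" && length(focal) != 1L)
    stop("lineage_specific events take exactly one focal taxon")
  if (kind == "convergent" && length(focal) != 2L)
    stop("convergent events take exactly two focal taxa")
  stopifnot(all(focal %in% aln$taxa))
  bg_cod <- codon_for_residue(background_res, code)
  f_cod <- codon_for_residue(focal_res, code)
  pos <- (column - 1L) * 3L + 1L
  for (tx in aln$taxa)
    substr(aln$seqs[[tx]], pos, pos + 2L) <-
      if (tx %in% focal) f_cod else bg_cod
  planted <- rbind(attr(aln, "planted"), data.frame(
    gene_id = aln$gene_id, kind = kind,
    focal = paste(focal, collapse = "+"), column = column,
    background_res = background_res, focal_res = focal_res,
    stringsAsFactors = FALSE))
  out <- codon_alignment(aln$seqs, gene_id = aln$gene_id, code = code)
  attr(out, "site_class") <- attr(aln, "site_class")
  attr(out, "planted") <- planted
  out
}

#' Default synthetic study configuration
#'
#' 50 genes of 300 codons on the default 8-taxon tree: 5 genes under
#' foreground acceleration (`omega_fg = 5` on the two marked highland
#' branches, background omega 0.2), 45 under a one-ratio purifying regime
#' (omega 0.2); two planted lineage-specific replacements (focal `C`) and
#' one planted convergent replacement (`C`+`E`); an annotation table over
#' all genes in which the planted term is carried by exactly the 5 selected
#' genes plus one background gene, among 12 decoy terms.
#'
#' @param n_genes total genes.
#' @param n_selected genes under foreground acceleration.
#' @param n_codons codons per gene.
#' @param omega_bg background (and null-regime) omega.
#' @param omega_fg foreground omega of the selected genes.
#' @param kappa transition/transversion ratio.
#' @param seed master seed; every byte of the study is reproducible from it.
#' @return a `study_config` list.
#' @export
default_study_config <- function(n_genes = 50L, n_selected = 5L,
                                 n_codons = 300L, omega_bg = 0.2,
                                 omega_fg = 5, kappa = 2, seed = 1L) {
  structure(list(
    tree = default_study_tree(), foreground = c("C", "E"),
    focal = "C", partner = "E",
    n_genes = n_genes, n_selected = n_selected, n_codons = n_codons,
    omega_bg = omega_bg, omega_fg = omega_fg, kappa = kappa,
    planted_term = "TERM_SEL", n_decoy_terms = 12L, seed = seed),
    class = "study_config")
}

#' Generate a complete synthetic ortholog study on disk
#'
#' Writes per-gene codon alignments (`alignments/gene_XXX.fasta`), the
#' marked species tree (`tree.nwk`), a gene-term annotation table
#' (`annotations.tsv`), and ground-truth tables (`truth_regimes.tsv`,
#' `truth_events.tsv`) under `out_dir`. Selected genes are the first
#' `n_selected` gene ids; planted substitution events go into background
#' genes so screen truth is independent of selection truth. Re-running with
#' the same config reproduces every byte.
#'
#' @param config a [default_study_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `paths`, `truth_regimes`, `truth_events`,
#'   `annotations`, and the planted `term`.
#' @export
generate_study <- function(config = default_study_config(), out_dir) {
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(config$seed)
  ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  selected <- ids[seq_len(config$n_selected)]
  regimes <- data.frame(gene_id = ids, regime = ifelse(ids %in% selected,
                                                       "branch", "null"),
                        omega_bg = config$omega_bg,
                        omega_fg = ifelse(ids %in% selected,
                                          config$omega_fg, config$omega_bg),
                        stringsAsFactors = FALSE)
  events <- NULL
  ## plant screen events into the last three genes (null regime)
  ev_genes <- utils::tail(ids, 3L)
  alns <- vector("list", config$n_genes)
  names(alns) <- ids
  for (g in ids) {
    regime <- if (g %in% selected)
      list(type = "branch", omega_bg = config$omega_bg,
           omega_fg = config$omega_fg)
    else list(type = "null", omega = config$omega_bg)
    aln <- simulate_codon_alignment(config$tree, config$n_codons, regime,
                                    kappa = config$kappa, gene_id = g)
    nc <- config$n_codons
    if (g == ev_genes[1L])
      aln <- plant_substitution(aln, max(1L, nc %/% 3L), "lineage_specific",
                                config$focal, "D", "E")
    if (g == ev_genes[2L])
      aln <- plant_substitution(aln, max(1L, nc %/% 5L), "lineage_specific",
                                config$focal, "A", "G")
    if (g == ev_genes[3L])
      aln <- plant_substitution(aln, max(1L, nc %/% 2L), "convergent",
                                c(config$focal, config$partner), "S", "P")
    if (!is.null(attr(aln, "planted")))
      events <- rbind(events, attr(aln, "planted"))
    alns[[g]] <- aln
    write_codon_alignment(aln, file.path(out_dir, "alignments",
                                         paste0(g, ".fasta")))
  }
  ## annotation table: planted term carries the selected genes (+1 decoy
  ## gene so K > k is possible); decoy terms annotate random gene subsets
  ann <- data.frame(gene = c(selected, ids[config$n_selected + 1L]),
                    term = config$planted_term, stringsAsFactors = FALSE)
  for (d in seq_len(config$n_decoy_terms)) {
    sz <- sample(seq(min(5L, config$n_genes), min(15L, config$n_genes)), 1L)
    ann <- rbind(ann, data.frame(gene = sample(ids, sz),
                                 term = sprintf("TERM_%02d", d)))
  }
  ## every gene annotated at least once (the universe is all annotated genes)
  bare <- setdiff(ids, ann$gene)
  if (length(bare) > 0L)
    ann <- rbind(ann, data.frame(gene = bare, term = "TERM_00"))
  ann <- ann[order(ann$term, ann$gene), ]
  paths <- list(
    alignments = file.path(out_dir, "alignments", paste0(ids, ".fasta")),
    tree = file.path(out_dir, "tree.nwk"),
    annotations = file.path(out_dir, "annotations.tsv"),
    truth_regimes = file.path(out_dir, "truth_regimes.tsv"),
    truth_events = file.path(out_dir, "truth_events.tsv"))
  write_species_tree(config$tree, paths$tree)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(regimes, paths$truth_regimes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(events, paths$truth_events, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth_regimes = regimes,
                 truth_events = events, annotations = ann,
                 term = config$planted_term, alignments = alns))
}
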