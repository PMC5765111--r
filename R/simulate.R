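# Ground-truth simulators: Yule trees, proteome evolution with
# substitutions and gene gain/loss, and character matrices under Mk,
# Brownian-motion and no-signal models. Every stochastic call takes an
# explicit seed; the same seed reproduces every output byte.

.AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
         "S","T","V","W","Y")

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from two lineages, the process waits an exponential time with
#' rate `k * birth_rate` while `k` lineages are extant, then splits a
#' uniformly chosen lineage; after reaching `n_tips` lineages one final
#' waiting time is added, so the expected root-to-tip depth is
#' `sum_{k=2}^{n} 1/(k * birth_rate)`. Tips are labelled `T1..Tn`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed RNG seed (required).
#' @return A binary rooted `phylo` tree with branch lengths.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_tips < 2L) stop("n_tips must be at least 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  set.seed(seed)
  nwk <- "(<L1>:@L1@,<L2>:@L2@)"
  act <- c("L1", "L2")
  lens <- c(L1 = 0, L2 = 0)
  k <- 2L; cnt <- 2L
  repeat {
    w <- stats::rexp(1L, k * birth_rate)
    lens[act] <- lens[act] + w
    if (k == n_tips) break
    i <- sample.int(k, 1L)
    old <- act[i]
    c1 <- paste0("L", cnt + 1L); c2 <- paste0("L", cnt + 2L)
    cnt <- cnt + 2L
    nwk <- sub(paste0("<", old, ">"),
               paste0("(<", c1, ">:@", c1, "@,<", c2, ">:@", c2, "@)"),
               nwk, fixed = TRUE)
    act <- c(act[-i], c1, c2)
    lens <- c(lens, stats::setNames(c(0, 0), c(c1, c2)))
    k <- k + 1L
  }
  for (nm in names(lens))
    nwk <- sub(paste0("@", nm, "@"), sprintf("%.12g", lens[[nm]]),
               nwk, fixed = TRUE)
  for (j in seq_along(act))
    nwk <- sub(paste0("<", act[j], ">"), paste0("T", j), nwk, fixed = TRUE)
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Evolve proteomes along a tree
#'
#' The root carries `n_genes` random sequences of `gene_length` residues
#' (uniform 20-letter composition). Along an edge of length `t` each gene
#' receives `Poisson(substitution_rate * t * gene_length)` substitutions
#' at uniformly chosen positions, each replacing the residue with a
#' uniformly chosen different one (so the per-site identity decays as
#' `1/20 + 19/20 * exp(-(20/19) * rate * t)`). Each gene is lost when it
#' receives at least one `Poisson(gene_loss_rate * t)` loss event, and
#' `Poisson(gene_gain_rate * t * n_genes)` fresh random genes are gained.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param n_genes genes at the root.
#' @param gene_length residues per gene.
#' @param substitution_rate substitutions per site per unit branch length.
#' @param gene_loss_rate,gene_gain_rate loss/gain events per gene per unit
#'   branch length.
#' @param seed RNG seed (required).
#' @return Named list (one per tip) of protein [seq_set] objects.
#' @export
evolve_proteomes <- function(tree, n_genes = 60L, gene_length = 200L,
                             substitution_rate = 0.1,
                             gene_loss_rate = 0, gene_gain_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (n_genes < 1L || gene_length < 1L) stop("need n_genes, gene_length >= 1")
  if (substitution_rate < 0 || gene_loss_rate < 0 || gene_gain_rate < 0)
    stop("rates must be non-negative")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  genome0 <- lapply(seq_len(n_genes), function(g)
    sample.int(20L, gene_length, replace = TRUE))
  names(genome0) <- sprintf("g%04d", seq_len(n_genes))
  gain_counter <- n_genes
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[root]] <- genome0
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    par <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]; t <- cw$edge.length[e]
    g <- genomes[[par]]
    # substitutions
    nsub <- stats::rpois(length(g), substitution_rate * t * gene_length)
    for (gi in which(nsub > 0L)) {
      sq <- g[[gi]]
      pos <- sample.int(gene_length, nsub[gi], replace = TRUE)
      for (p in pos) {
        r <- sample.int(19L, 1L)
        sq[p] <- if (r < sq[p]) r else r + 1L   # uniform over the other 19
      }
      g[[gi]] <- sq
    }
    # losses
    if (gene_loss_rate > 0 && length(g)) {
      lost <- stats::rpois(length(g), gene_loss_rate * t) > 0L
      g <- g[!lost]
    }
    # gains
    if (gene_gain_rate > 0) {
      ngain <- stats::rpois(1L, gene_gain_rate * t * n_genes)
      if (ngain > 0L) {
        fresh <- lapply(seq_len(ngain), function(x)
          sample.int(20L, gene_length, replace = TRUE))
        names(fresh) <- sprintf("g%04d", gain_counter + seq_len(ngain))
        gain_counter <- gain_counter + ngain
        g <- c(g, fresh)
      }
    }
    genomes[[ch]] <- g
  }
  out <- vector("list", ntip)
  names(out) <- tree$tip.label
  for (i in seq_len(ntip)) {
    g <- genomes[[i]]
    if (length(g) == 0L)
      stop("tip ", tree$tip.label[i], " lost every gene; lower the loss rate")
    seqs <- vapply(g, function(sq) paste(.AA[sq], collapse = ""),
                   character(1L))
    out[[i]] <- seq_set(seqs, strain_id = tree$tip.label[i],
                        alphabet = "protein")
  }
  out
}

#' Evolve a character matrix along a tree
#'
#' Models: `"mk"` is the symmetric 2-state Markov chain with rate `q`
#' (flip probability `(1 - exp(-2 q t)) / 2` along an edge of length
#' `t`), yielding binary characters; `"bm"` is Brownian motion with root
#' value 0 and Gaussian increments of variance `sigma2 * t`, yielding
#' continuous characters; `"noise"` draws iid standard-normal values per
#' tip, i.e. characters with no phylogenetic signal (the null of the
#' tip-permutation test).
#'
#' @param tree `phylo` tree with branch lengths.
#' @param n_chars number of characters.
#' @param model `"mk"`, `"bm"` or `"noise"`.
#' @param q Mk flip rate.
#' @param sigma2 BM variance per unit branch length.
#' @param seed RNG seed (required).
#' @param prefix character-name prefix.
#' @param panel optional panel label applied to all generated characters.
#' @return A [character_table] over the tree's tips.
#' @export
evolve_characters <- function(tree, n_chars, model = c("mk", "bm", "noise"),
                              q = 1, sigma2 = 1, seed, prefix = NULL,
                              panel = NULL) {
  if (missing(seed)) stop("seed is required")
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cw <- ape::reorder.phylo(tree, "cladewise")
  vals <- matrix(NA_real_, ntip + tree$Nnode, n_chars)
  if (model == "noise") {
    tipvals <- matrix(stats::rnorm(ntip * n_chars), ntip, n_chars)
  } else {
    vals[root, ] <- if (model == "mk")
      stats::rbinom(n_chars, 1L, 0.5) else 0
    for (e in seq_len(nrow(cw$edge))) {
      par <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]; t <- cw$edge.length[e]
      if (model == "mk") {
        pflip <- (1 - exp(-2 * q * t)) / 2
        flip <- stats::rbinom(n_chars, 1L, pflip)
        vals[ch, ] <- (vals[par, ] + flip) %% 2
      } else {
        vals[ch, ] <- vals[par, ] +
          stats::rnorm(n_chars, 0, sqrt(sigma2 * t))
      }
    }
    tipvals <- vals[seq_len(ntip), , drop = FALSE]
  }
  if (is.null(prefix)) prefix <- model
  dimnames(tipvals) <- list(tree$tip.label,
                            sprintf("%s_%03d", prefix, seq_len(n_chars)))
  kinds <- rep(if (model == "mk") "binary" else "continuous", n_chars)
  character_table(tipvals, kinds,
                  panels = if (is.null(panel)) NULL else rep(panel, n_chars))
}

#' Generate a self-contained synthetic study
#'
#' Builds a small end-to-end fixture in `dir`: a true 12-tip Yule tree,
#' per-tip proteome FASTA files evolved along it (with mild gene gain and
#' loss), a 40-character table spanning four panels (binary Mk
#' characters, two Brownian panels of differing signal strength, and
#' no-signal noise characters), and three alternative "gene" trees
#' inferred from small, noisier proteome simulations on the same true
#' tree.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed (required).
#' @param n_tips tips in the study (default 12).
#' @return Invisibly, a list of the paths written.
#' @export
demo_generate <- function(dir, seed, n_tips = 12L) {
  if (missing(seed)) stop("seed is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_tree(n_tips, birth_rate = 1, seed = seed)
  tree_path <- file.path(dir, "true_tree.nwk")
  write_newick(tree, tree_path)
  prot <- evolve_proteomes(tree, n_genes = 20L, gene_length = 100L,
                           substitution_rate = 0.1,
                           gene_loss_rate = 0.02, gene_gain_rate = 0.02,
                           seed = seed + 1L)
  fasta_paths <- vapply(names(prot), function(tp) {
    p <- file.path(dir, paste0(tp, ".faa"))
    write_fasta(prot[[tp]], p)
    p
  }, character(1L))
  panels <- list(
    evolve_characters(tree, 10L, "mk", q = 0.5, seed = seed + 2L,
                      prefix = "pheno", panel = "phenotype"),
    evolve_characters(tree, 10L, "bm", sigma2 = 4, seed = seed + 3L,
                      prefix = "fa", panel = "fatty_acids"),
    evolve_characters(tree, 10L, "bm", sigma2 = 1, seed = seed + 4L,
                      prefix = "cog", panel = "COGs"),
    evolve_characters(tree, 10L, "noise", seed = seed + 5L,
                      prefix = "noise", panel = "noise"))
  tab <- character_table(
    do.call(cbind, lapply(panels, unclass)),
    kinds = unlist(lapply(panels, attr, "kinds")),
    panels = unlist(lapply(panels, attr, "panels")))
  tab_path <- file.path(dir, "characters.tsv")
  write_character_table(tab, tab_path)
  gene_paths <- character(3L)
  for (g in 1:3) {
    gp <- evolve_proteomes(tree, n_genes = 6L, gene_length = 150L,
                           substitution_rate = 0.25, seed = seed + 10L + g)
    # saturated pairs hit the d_max ceiling, as real single genes would
    dm <- suppressWarnings(distance_matrix(gp))
    gt <- nj_tree(dm)
    gene_paths[g] <- file.path(dir, sprintf("genetree_%d.nwk", g))
    write_newick(gt, gene_paths[g])
  }
  invisible(list(tree = tree_path, fastas = fasta_paths,
                 characters = tab_path, gene_trees = gene_paths))
}
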