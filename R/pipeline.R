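#' Run the full phylogenomic analysis pipeline
#'
#' Orchestrates every stage on user data: GBDP distances from per-strain
#' FASTA files, pseudo-bootstrap replicates, NJ + balanced-minimum-
#' evolution tree with support values, dDDH estimates and genomic-species
#' delineation, the tip-permutation conservation test on a character
#' table, Robinson-Foulds congruence of the inferred tree with any
#' user-supplied alternative trees (with principal coordinates), and the
#' chi-squared screen over binary characters. A manifest recording
#' inputs, parameters, seeds and output checksums is written last, so a
#' rerun with the same config reproduces every output byte.
#'
#' @param config named list, or path of a YAML file holding one.
#'   Recognized keys: `genomes_dir` (directory of FASTA files, required),
#'   `alphabet` (`"protein"`/`"dna"`, default protein), `out_dir`
#'   (required), `character_table` (TSV path, optional), `trees` (named
#'   list of Newick paths, optional), `seed` (required), and the stage
#'   parameters `k`, `x_drop`, `min_len`, `min_score`, `d_max`, `d70`,
#'   `ddh_threshold`, `bootstrap_B`, `perms_M`, `k_bins`, `rf_mode`.
#'   Unknown keys are rejected.
#' @return Invisibly, a list with the main in-memory results and the
#'   paths of the files written.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(genomes_dir = NULL, alphabet = "protein",
                   out_dir = NULL, character_table = NULL, trees = NULL,
                   seed = NULL, k = NULL, x_drop = 20, min_len = 10L,
                   min_score = 30, d_max = 5.0, d70 = 0.09,
                   ddh_threshold = 70, bootstrap_B = 100L,
                   perms_M = 10000L, k_bins = 10L, rf_mode = "relative")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (req in c("genomes_dir", "out_dir", "seed"))
    if (is.null(cfg[[req]])) stop("config key '", req, "' is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- new.env()   # mutated from inside the staged expressions

  genomes <- stage("read-genomes", {
    files <- sort(list.files(cfg$genomes_dir,
                             pattern = "\\.(fa|faa|fna|fasta)$",
                             full.names = TRUE))
    if (length(files) < 2L) stop("need at least two FASTA files")
    gs <- lapply(files, read_fasta, alphabet = cfg$alphabet)
    ids <- vapply(gs, `[[`, character(1L), "strain_id")
    if (anyDuplicated(ids)) stop("duplicate strain id: ",
                                 ids[duplicated(ids)][1L])
    gs
  })

  dm <- stage("distances", {
    m <- distance_matrix(genomes, k = cfg$k, x_drop = cfg$x_drop,
                         min_len = cfg$min_len, min_score = cfg$min_score,
                         d_max = cfg$d_max)
    paths$distances <- file.path(cfg$out_dir, "distances.phylip")
    write_phylip_distances(m, paths$distances)
    m
  })

  tree <- stage("tree", {
    main <- bme_refine(nj_tree(dm), dm)
    reps <- pseudo_bootstrap(dm, B = cfg$bootstrap_B, seed = cfg$seed,
                             d_max = cfg$d_max)
    rep_trees <- lapply(reps, function(r) bme_refine(nj_tree(r), r))
    main <- support_values(main, rep_trees)
    paths$tree <- file.path(cfg$out_dir, "tree.nwk")
    write_newick(main, paths$tree)
    main
  })

  ddh <- stage("ddh", {
    dd <- ddh_estimate(dm, d70 = cfg$d70)
    diag(dd) <- 100
    sp <- delineate_species(dd, threshold = cfg$ddh_threshold)
    det <- attr(dm, "details")
    tab <- data.frame(a = det$a, b = det$b, d = det$d,
                      ddh = ddh_estimate(det$d, d70 = cfg$d70),
                      same_species = sp[det$a] == sp[det$b])
    paths$ddh <- file.path(cfg$out_dir, "ddh.tsv")
    utils::write.table(tab, paths$ddh, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    list(matrix = dd, species = sp, pairs = tab)
  })

  conserve <- NULL
  if (!is.null(cfg$character_table)) {
    conserve <- stage("conserve", {
      tab <- read_character_table(cfg$character_table)
      res <- tip_permutation_test(tree, tab, M = cfg$perms_M,
                                  seed = cfg$seed + 1L,
                                  k_bins = cfg$k_bins)
      paths$conserve <- file.path(cfg$out_dir, "conserve.tsv")
      utils::write.table(res, paths$conserve, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      res
    })
  }

  compare <- NULL
  if (!is.null(cfg$trees)) {
    compare <- stage("compare-trees", {
      alt <- lapply(cfg$trees, read_newick)
      all_trees <- c(list(GBDP = tree), alt)
      rf <- tree_distance_matrix(all_trees, mode = cfg$rf_mode)
      fit <- pcoa(rf, n_axes = 2L)
      paths$rf <- file.path(cfg$out_dir, "rf.tsv")
      utils::write.table(rf, paths$rf, sep = "\t", quote = FALSE)
      paths$coords <- file.path(cfg$out_dir, "coords.tsv")
      utils::write.table(fit$coords, paths$coords, sep = "\t",
                         quote = FALSE)
      list(rf = rf, pcoa = fit)
    })
  }

  pheno <- NULL
  if (!is.null(cfg$character_table)) {
    tabk <- read_character_table(cfg$character_table)
    if (sum(attr(tabk, "kinds") == "binary") >= 2L) {
      pheno <- stage("pheno", {
        scr <- chi2_screen(tabk)
        paths$pheno <- file.path(cfg$out_dir, "pheno.tsv")
        utils::write.table(scr, paths$pheno, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        scr
      })
    }
  }

  stage("manifest", {
    manifest <- list(
      parameters = cfg[setdiff(names(cfg), c("trees", "out_dir"))],
      inputs = list(genomes = vapply(genomes, `[[`, character(1L),
                                     "strain_id"),
                    character_table = cfg$character_table,
                    trees = if (is.null(cfg$trees)) NULL
                            else unlist(cfg$trees)),
      outputs = lapply(as.list(paths), function(p)
        unname(tools::md5sum(p))))
    paths$manifest <- file.path(cfg$out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, paths$manifest)
  })

  invisible(list(distances = dm, tree = tree, ddh = ddh,
                 conserve = conserve, compare = compare, pheno = pheno,
                 paths = as.list(paths)))
}
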