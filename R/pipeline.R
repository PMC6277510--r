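#' Default pipeline configuration
#'
#' The demo study conditions: 8 taxa per group, 200 characters, 1% flip
#' noise, 100 bootstrap replicates, a 4-genome family specification with
#' core, 3-genome, 2-genome and unique families, and a Tupanvirus-like
#' donor mix for the rhizome stage. Any field can be overridden by the
#' `config` argument of [run_pipeline()].
#'
#' @return Named list of stage parameters.
#' @export
default_run_config <- function() {
  list(
    seed = 11,
    n_taxa_per_group = 8,
    n_characters = 200,
    gain_rate = 0.01,
    loss_rate = 0.01,
    age_noise = 0.05,
    universal_only = FALSE,
    n_starts = 3,
    rearrangement = "SPR",
    bootstrap_reps = 100,
    bootstrap_rearrangement = "NNI",
    k_concavity = 2,
    axes = 3,
    linkage = "average",
    family_spec = default_family_spec(),
    donor_props = c(virus = 0.51, eukaryota = 0.11, bacteria = 0.08,
                    archaea = 0.002),
    n_rhizome_genes = 300,
    inputs = list()
  )
}

# Four small genomes named after the study organisms' roles, with planted
# families at every sharing level.
default_family_spec <- function() {
  g <- c("bacterium", "archaeon", "eukaryote", "giantvirus")
  all4 <- paste(g, collapse = ";")
  bind_rows(
    tibble(family = sprintf("core%02d", 1:2), genomes = all4,
           genes_per_genome = 1L, length = 180L, divergence = 0.2),
    tibble(family = sprintf("span3_%02d", 1:2),
           genomes = c("bacterium;archaeon;giantvirus",
                       "archaeon;eukaryote;giantvirus"),
           genes_per_genome = 1L, length = 160L, divergence = 0.2),
    tibble(family = sprintf("span2_%02d", 1:3),
           genomes = c("bacterium;giantvirus", "eukaryote;giantvirus",
                       "bacterium;archaeon"),
           genes_per_genome = 1L, length = 150L, divergence = 0.2),
    tibble(family = sprintf("uniq_%s", g), genomes = g,
           genes_per_genome = 3L, length = 140L, divergence = 0.1)
  )
}

#' Run the whole synthetic evidence chain
#'
#' Orchestrates all stages on simulated data with known truth: character
#' matrix generation, informative-character filtering and serialization,
#' maximum parsimony search with bootstrap and Lundberg rooting,
#' character-fit-versus-age table, evolutionary PCoA with group separation,
#' Pearson-distance phyletic clustering with the four-branch purity check,
#' four-genome pangenome partitioning, and best-hit rhizome aggregation.
#' All outputs are plain text files under `out_dir`, each carrying a
#' provenance header (or accompanied by the manifest for formats without
#' comments); a JSONL log records seed, package version and per-stage
#' timings. Re-running with the same config is bit-reproducible.
#'
#' @param config named list overriding [default_run_config()] fields, or a
#'   path to a YAML file of such overrides.
#' @param out_dir output directory (created if needed).
#' @return List of class `truc_run` with the main stage results (`sim`,
#'   `mp`, `boot`, `rooted`, `fit`, `pcoa`, `separation`, `fourbranch`,
#'   `pangenome`, `rhizome`) and `files` (named vector of output paths).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$donor_props)) {
      config$donor_props <- unlist(config$donor_props)
    }
    if (!is.null(config$family_spec)) {
      config$family_spec <- bind_rows(config$family_spec)
    }
  }
  cfg <- utils::modifyList(default_run_config(), config)
  # fail before any stage runs if a declared input is missing
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "family_spec")], cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "run_log.jsonl")
  unlink(log_path)
  log_stage <- function(stage, t0) {
    cat(jsonlite::toJSON(list(stage = stage, seed = cfg$seed,
                              version = as.character(
                                utils::packageVersion("trucphylo")),
                              config_md5 = cfg_hash,
                              elapsed_s = round(
                                as.numeric(Sys.time()) - t0, 3)),
                         auto_unbox = TRUE),
        "\n", file = log_path, append = TRUE, sep = "")
  }
  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
    log_stage(stage, t0)
    res
  }
  files <- c(config = cfg_path, log = log_path)
  out <- list(config = cfg, config_md5 = cfg_hash)
  hdr <- sprintf("config_md5=%s", cfg_hash)

  out$sim <- run_stage("simulate", function() {
    sim_cfg <- sim_config(n_taxa_per_group = cfg$n_taxa_per_group,
                          n_characters = cfg$n_characters,
                          gain_rate = cfg$gain_rate,
                          loss_rate = cfg$loss_rate,
                          age_noise = cfg$age_noise,
                          family_spec = cfg$family_spec,
                          donor_props = cfg$donor_props,
                          seed = cfg$seed)
    sim_presence_matrix(sim_cfg)
  })

  out$pa <- run_stage("matrix", function() {
    pa <- out$sim$pa
    if (isTRUE(cfg$universal_only)) pa <- select_universal(pa)
    pa <- filter_parsimony_informative(pa)
    files["matrix_tsv"] <<- write_pa_tsv(
      pa, file.path(out_dir, "matrix.tsv"), seed = cfg$seed)
    files["matrix_nexus"] <<- write_nexus(
      pa, file.path(out_dir, "matrix.nex"), seed = cfg$seed)
    pa
  })

  out$mp <- run_stage("mptree", function() {
    mp <- mp_search(out$pa, n_starts = cfg$n_starts,
                    rearrangement = cfg$rearrangement, seed = cfg$seed)
    p <- file.path(out_dir, "mp_trees.nwk")
    ape::write.tree(do.call(c, lapply(mp$trees, identity)), file = p)
    files["mp_trees"] <<- p
    mp
  })

  out$boot <- run_stage("bootstrap", function() {
    boot <- bootstrap_support(out$pa, out$mp$trees[[1]],
                              reps = cfg$bootstrap_reps, seed = cfg$seed,
                              rearrangement = cfg$bootstrap_rearrangement)
    p <- file.path(out_dir, "mp_tree_support.nwk")
    ape::write.tree(boot$tree, file = p)
    files["support_tree"] <<- p
    boot
  })

  out$rooted <- run_stage("rooting", function() {
    rooted <- lundberg_root(out$mp$trees[[1]], out$pa)
    p <- file.path(out_dir, "mp_tree_rooted.nwk")
    ape::write.tree(rooted, file = p)
    files["rooted_tree"] <<- p
    rooted
  })

  out$fit <- run_stage("charfit", function() {
    fit <- character_fit(out$mp$trees[[1]], out$pa, k = cfg$k_concavity)
    files["fit_table"] <<- write_fit_table(
      fit_vs_age(fit), file.path(out_dir, "fit_vs_age.tsv"), seed = cfg$seed)
    fit
  })

  out$pcoa <- run_stage("evopcoa", function() {
    pc <- evo_pcoa(out$pa, k = cfg$axes)
    files["pcoa"] <<- write_pcoa_tsv(pc, file.path(out_dir, "evo_pcoa.tsv"),
                                     seed = cfg$seed)
    pc
  })
  out$separation <- group_separation(out$pcoa)

  out$fourbranch <- run_stage("cluster", function() {
    d <- pearson_distance(out$pa)
    files["distances"] <<- write_distance_tsv(
      d, file.path(out_dir, "pearson_distances.tsv"), seed = cfg$seed)
    hc <- phyletic_cluster(d, linkage = cfg$linkage)
    files["dendrogram"] <<- write_dendrogram_newick(
      hc, file.path(out_dir, "dendrogram.nwk"))
    four_branch_check(hc, pa_groups(out$pa))
  })

  out$pangenome <- run_stage("pangenome", function() {
    sim_cfg <- sim_config(family_spec = cfg$family_spec, seed = cfg$seed)
    gen <- sim_genomes(sim_cfg)
    files["genomes_fasta"] <<- write_fasta_genes(
      gen$genes, file.path(out_dir, "genomes.faa"))
    hits <- all_vs_all_homology(gen$genes)
    fams <- build_families(hits, gen$genes)
    part <- partition_pangenome(fams)
    files["pangenome_tsv"] <<- write_partition(
      part, file.path(out_dir, "pangenome.tsv"), seed = cfg$seed)
    files["pangenome_json"] <<- write_partition(
      part, file.path(out_dir, "pangenome.json"), format = "json")
    part
  })

  out$rhizome <- run_stage("rhizome", function() {
    gene_ids <- sprintf("gv|gene%04d", seq_len(cfg$n_rhizome_genes))
    sim_cfg <- sim_config(donor_props = cfg$donor_props, seed = cfg$seed)
    sh <- sim_hit_table(sim_cfg, gene_ids)
    cls <- classify_best_hits(sh$hits, sh$query_taxonomy, units = gene_ids)
    agg <- aggregate_rhizome(cls, genome_size = length(gene_ids))
    files["circos"] <<- write_circos_table(
      list(giantvirus = agg), file.path(out_dir, "rhizome_circos.tsv"),
      seed = cfg$seed)
    agg
  })

  manifest <- tibble(file = basename(unname(files)),
                     config_md5 = cfg_hash)
  mpath <- file.path(out_dir, "MANIFEST.tsv")
  write_lines_with_header(
    c("file\tconfig_md5", paste(manifest$file, manifest$config_md5,
                                sep = "\t")),
    mpath, seed = cfg$seed, extra = hdr)
  files["manifest"] <- mpath
  out$files <- files
  structure(out, class = "truc_run")
}

#' @export
print.truc_run <- function(x, ...) {
  cat("<truc_run>\n")
  cat(sprintf("  MP length %d; groups monophyletic: %s\n", x$mp$length,
              paste(groups_monophyletic(x$mp$trees[[1]],
                                        pa_groups(x$pa))$monophyletic,
                    collapse = " ")))
  cat(sprintf("  cluster purity %.3f; min group separation %.3f\n",
              x$fourbranch$purity, min(x$separation$score)))
  cat(sprintf("  %d output files under %s\n", length(x$files),
              dirname(x$files[["config"]])))
  invisible(x)
}
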