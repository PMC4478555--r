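## End-to-end orchestration: detect -> map -> fit -> ancestral ->
## structure -> classify, with every stage communicating through on-disk
## artifacts so any stage can be rerun independently.

#' Run the element-survey pipeline end to end
#'
#' Stages, in order: read inputs (genome FASTA + Newick tree, or a
#' simulated dataset written first when `config$simulate` is given);
#' dispersed-repeat detection on the reference strain; homolog search of
#' the top family across all strains; flank anchoring and
#' presence/absence matrix; one- and two-rate turnover fits with
#' likelihood-ratio test; root ancestral states; hairpin partition and
#' loop/stem enrichment; residue classification. All numeric outputs are
#' reproducible from `config$seed`.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{genomes, tree}{paths to a multi-record FASTA and a Newick
#'       file; alternatively}
#'     \item{simulate}{a list of [sim_params()] arguments — the dataset
#'       is simulated and written under `out_dir` first.}
#'     \item{reference}{reference strain id (default: first genome).}
#'     \item{min_len, min_gc}{detection parameters (defaults 30, 0.30).}
#'     \item{min_identity, min_coverage}{homolog search thresholds
#'       (defaults 0.90, 0.95).}
#'     \item{flank, flank_min_identity}{anchoring parameters
#'       (defaults 100, 0.80).}
#'     \item{root_prior}{turnover root prior (default "stationary").}
#'     \item{seed}{integer seed (default 1).}
#'     \item{verbose}{logical (default TRUE).}
#'   }
#' @return Invisibly, a list with the per-stage results (`families`,
#'   `matrix`, `fit_one`, `fit_two`, `lrt`, `ancestral`, `partition`,
#'   `enrichment`, `classification`) and the paths of the artifacts
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- function(name, default = NULL) config[[name]] %||% default
  out_dir <- cfg("out_dir") %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(cfg("verbose", TRUE))
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  seed <- cfg("seed", 1L)
  set.seed(seed)

  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## ---- inputs ----------------------------------------------------------
  if (!is.null(cfg("simulate"))) {
    sim <- stage("simulate", {
      sp <- do.call(sim_params, c(cfg("simulate"), list(seed = seed)))
      simulate_dataset(sp)
    })
    genomes <- sim$genomes
    tree <- sim$truth$tree
    write_genomes(genomes, file.path(out_dir, "genomes.fa"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_pa_matrix(sim$truth$matrix, file.path(out_dir, "truth_matrix.tsv"))
  } else {
    genomes <- stage("read_genomes", {
      p <- cfg("genomes") %||% stop("config$genomes is required")
      if (!file.exists(p)) stop("genome FASTA not found: ", p)
      read_genomes(p)
    })
    tree <- stage("read_tree", {
      p <- cfg("tree") %||% stop("config$tree is required")
      if (!file.exists(p)) stop("tree file not found: ", p)
      read_strain_tree(p)
    })
  }
  strains <- names(genomes)
  reference <- cfg("reference", strains[1L])

  ## ---- detect ----------------------------------------------------------
  ## a dispersed repeat needs >= 2 copies in one genome; when the chosen
  ## reference carries too few, fall back to the other strains in order
  fams <- stage("detect", {
    out <- NULL
    for (st in unique(c(reference, strains))) {
      f <- suppressWarnings(find_dispersed_repeats(
        genomes[[st]],
        min_len = cfg("min_len", 30L), min_gc = cfg("min_gc", 0.30)))
      if (length(f) > 0L) { out <- f; reference <- st; break }
    }
    if (is.null(out)) stop("no repeat family in any strain")
    out
  })
  write_occurrences(do.call(rbind, lapply(fams, `[[`, "copies")),
                    file.path(out_dir, "occurrences.tsv"))
  fam_tab <- data.frame(
    family_id = vapply(fams, `[[`, "", "family_id"),
    length = vapply(fams, `[[`, 0L, "length"),
    n_copies = vapply(fams, `[[`, 0L, "n_copies"),
    gc_percent = vapply(fams, `[[`, 0, "gc_percent"),
    tsd = vapply(fams, `[[`, "", "tsd"),
    representative = vapply(fams, `[[`, "", "representative"))
  write.table(fam_tab, file.path(out_dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  query <- fams[[1L]]$representative

  ## ---- map -------------------------------------------------------------
  occ <- stage("map", do.call(rbind, lapply(genomes, function(g)
    search_homologs(query, g, min_identity = cfg("min_identity", 0.90),
                    min_coverage = cfg("min_coverage", 0.95)))))
  positions <- stage("anchor", anchor_positions(
    occ, genomes, flank = cfg("flank", 100L),
    flank_min_identity = cfg("flank_min_identity", 0.80),
    reference = reference))
  if (length(positions) == 0L) stop("stage 'anchor' produced no position")
  mat <- build_pa_matrix(positions, strains)
  write_pa_matrix(mat, file.path(out_dir, "matrix.tsv"))

  ## ---- fit -------------------------------------------------------------
  root_prior <- cfg("root_prior", "stationary")
  fit_one <- stage("fit", fit_turnover(tree, mat, model = "one_rate",
                                       root_prior = root_prior))
  fit_two <- fit_turnover(tree, mat, model = "two_rate",
                          root_prior = root_prior)
  lrt <- likelihood_ratio_test(fit_one, fit_two)
  fit_json <- list(
    one_rate = list(mu = unname(coef(fit_one)[["mu"]]),
                    se = unname(fit_one$se[["gain"]]),
                    lnL = fit_one$logLik),
    two_rate = list(gain = unname(fit_two$rates[["gain"]]),
                    loss = unname(fit_two$rates[["loss"]]),
                    se_gain = unname(fit_two$se[["gain"]]),
                    se_loss = unname(fit_two$se[["loss"]]),
                    lnL = fit_two$logLik),
    lrt = list(statistic = lrt$statistic, df = lrt$df,
               p_value = lrt$p_value),
    n_positions = nrow(mat), root_prior = root_prior, seed = seed)
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- ancestral -------------------------------------------------------
  anc <- stage("ancestral", ancestral_posteriors(fit_two, nodes = "root"))
  anc_tab <- data.frame(position = rownames(anc),
                        posterior_present = anc[, "root"],
                        favors = ifelse(anc[, "root"] > 0.5, "presence",
                                        ifelse(anc[, "root"] < 0.5,
                                               "absence", "tie")))
  write.table(anc_tab, file.path(out_dir, "ancestral.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- structure -------------------------------------------------------
  partition <- stage("structure", fold_hairpin(query))
  homologs <- unlist(lapply(positions, function(p)
    p$per_strain_element[!is.na(p$per_strain_element)]))
  changes <- count_partition_changes(homologs, query, partition)
  enr <- partition_enrichment_test(changes[["loop"]], changes[["stem"]],
                                   length(partition$loop),
                                   length(partition$stem))
  jsonlite::write_json(
    list(n_loop_sites = length(partition$loop),
         n_stem_sites = length(partition$stem),
         loop_changes = changes[["loop"]], stem_changes = changes[["stem"]],
         fisher_p = enr$p_value, mode = enr$mode),
    file.path(out_dir, "structure.json"), auto_unbox = TRUE, digits = NA)

  ## ---- classify --------------------------------------------------------
  tsd <- fams[[1L]]$tsd
  classification <- stage("classify", {
    if (nzchar(tsd)) {
      cls <- lapply(positions, function(p)
        cbind(position = p$position_id,
              classify_position(p$per_strain_residue, tsd, query)))
      do.call(rbind, cls)
    } else NULL
  })
  if (!is.null(classification))
    write.table(classification, file.path(out_dir, "classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  say("done; artifacts in ", out_dir)
  invisible(list(families = fams, positions = positions, matrix = mat,
                 fit_one = fit_one, fit_two = fit_two, lrt = lrt,
                 ancestral = anc_tab, partition = partition,
                 enrichment = enr, classification = classification,
                 out_dir = out_dir))
}
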