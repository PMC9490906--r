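default_params <- function() {
  list(
    identify = list(min_fpkm = 0.1, min_fraction = 0.2, min_len = 200),
    pair = list(rho_min = 0.9, alpha = 0.05, cis_window = 100000,
                ndg_max = -0.1, energy_on_cis = FALSE, fdr = FALSE),
    popgen = list(window = 50000, min_alleles = 4),
    cerna = list(rho_min = 0.5, alpha = 0.05, sign = "negative",
                 expectation_max = 5),
    assoc = list(n_pcs = 3, maf = 0.05, ne = NULL, window = 5e6),
    conserve = list(threshold = 0.6, formula = "product")
  )
}

#' Validate a pipeline configuration
#'
#' A run configuration is a named list (or YAML file) with `out_dir`, `seed`,
#' either `simulate: true` (inputs are generated) or an `inputs` block of
#' file paths, and optional per-stage parameter blocks overriding the
#' defaults (all discovery/pairing/popgen/ceRNA/association/conservation
#' thresholds). Referenced input files must exist at validation time.
#'
#' @param config named list or path to a YAML file.
#' @return The normalised config list (errors describe the first problem).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stopf("config needs out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  config$simulate <- isTRUE(config$simulate) || is.null(config$inputs)
  if (!config$simulate) {
    needed <- c("reference", "assembly", "expr", "coding_calls", "vcf",
                "groups", "array", "array_positions", "pheno", "binding_lnc",
                "binding_mrna", "energy", "homology", "qtl", "introgression")
    miss <- setdiff(needed, names(config$inputs))
    if (length(miss)) stopf("inputs block missing: %s", paste(miss, collapse = ", "))
    absent <- Filter(function(f) !file.exists(config$inputs[[f]]), needed)
    if (length(absent))
      stopf("input file(s) not found: %s",
            paste(unlist(config$inputs[absent]), collapse = ", "))
  }
  defaults <- default_params()
  for (stage in names(defaults)) {
    user <- config[[stage]] %||% list()
    merged <- defaults[[stage]]
    merged[names(user)] <- user
    config[[stage]] <- merged
  }
  config
}

stage_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> identify -> pair -> popgen -> cerna ->
#' assoc -> conserve, writing each stage's tables under `out_dir` and a
#' `manifest.json` recording stage order, input checksums, row counts,
#' parameters and wall time. A stage failure stops the run with the manifest
#' written up to that point. With `resume = TRUE`, stages whose recorded
#' input checksums are unchanged and whose outputs exist are skipped.
#'
#' @param config run configuration (list or YAML path); see
#'   [validate_config()].
#' @param resume skip stages with unchanged inputs (default `FALSE`).
#' @return (invisibly) the manifest list.
#' @export
run_all <- function(config, resume = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  manifest_path <- p("manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("spikelnc")),
                   seed = config$seed, stages = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  run_stage <- function(name, inputs, outputs, params, fun) {
    sums <- stage_checksums(inputs)
    old <- old_manifest$stages[[name]]
    if (resume && !is.null(old) && identical(old$input_md5, sums) &&
        all(file.exists(outputs))) {
      manifest$stages[[name]] <<- c(old, list(skipped = TRUE))
      message(sprintf("[%s] unchanged, skipped", name))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(failed = TRUE,
                                       error = conditionMessage(res))
      flush_manifest()
      stopf("stage %s failed: %s", name, conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(
      input_md5 = sums, params = params,
      rows_out = res,
      wall_seconds = round(proc.time()[["elapsed"]] - t0, 2))
    flush_manifest()
    invisible(NULL)
  }

  if (config$simulate) {
    run_stage("simulate", character(0),
              p(c("assembly.gtf", "expr.tsv", "panel.vcf")),
              list(seed = config$seed), function() {
      cfg <- do.call(simulation_config,
                     c(list(seed = config$seed), config$simulate_params %||% list()))
      sim <- simulate_all(cfg, out_dir)
      list(lncrnas = length(sim$truth$lncrna_ids))
    })
    inputs <- setNames(
      p(c("reference.gtf", "assembly.gtf", "expr.tsv", "coding_calls.tsv",
          "panel.vcf", "groups.tsv", "array.tsv", "array_positions.tsv",
          "pheno.tsv", "binding_lnc.tsv", "binding_mrna.tsv", "energy.tsv",
          "homology_hits.tsv", "qtl.bed", "introgression.bed")),
      c("reference", "assembly", "expr", "coding_calls", "vcf", "groups",
        "array", "array_positions", "pheno", "binding_lnc", "binding_mrna",
        "energy", "homology", "qtl", "introgression"))
  } else {
    inputs <- unlist(config$inputs)
  }

  env <- new.env()
  run_stage("identify", unname(inputs[c("reference", "assembly", "expr",
                                        "coding_calls")]),
            p("candidates.tsv"), config$identify, function() {
    env$reference <- read_gtf(inputs[["reference"]])
    env$assembly <- read_gtf(inputs[["assembly"]])
    env$expr <- read_expression(inputs[["expr"]])
    calls <- identify_lncrnas(env$assembly, env$reference, env$expr,
                              read_tsv_file(inputs[["coding_calls"]]),
                              min_len = config$identify$min_len,
                              min_fpkm = config$identify$min_fpkm,
                              min_fraction = config$identify$min_fraction)
    env$candidates <- calls$candidates
    write_tsv_file(calls$candidates, p("candidates.tsv"))
    as.list(calls$funnel)
  })

  run_stage("pair", unname(inputs[c("assembly", "expr", "energy")]),
            p("pairs.tsv"), config$pair, function() {
    env$mrnas <- subset_transcripts(
      env$reference, env$reference$transcripts$transcript_id)
    env$pairs <- build_pairs(env$candidates, env$mrnas, env$expr,
                             read_tsv_file(inputs[["energy"]]),
                             rho_min = config$pair$rho_min,
                             alpha = config$pair$alpha,
                             cis_window = config$pair$cis_window,
                             ndg_max = config$pair$ndg_max,
                             energy_on_cis = config$pair$energy_on_cis,
                             fdr = config$pair$fdr)
    write_tsv_file(env$pairs, p("pairs.tsv"))
    list(pairs = nrow(env$pairs), cis = sum(env$pairs$mode == "cis"),
         trans = sum(env$pairs$mode == "trans"))
  })

  run_stage("popgen", unname(inputs[c("vcf", "groups")]),
            p(c("pi.tsv", "fst.tsv", "density.tsv", "shifts.tsv")),
            config$popgen, function() {
    env$panel <- read_vcf(inputs[["vcf"]], inputs[["groups"]])
    feats <- data.frame(feature_id = env$candidates$transcript_id,
                        chrom = env$candidates$chrom,
                        start = env$candidates$start,
                        end = env$candidates$end, stringsAsFactors = FALSE)
    names(feats)[1] <- "name"
    pi_tab <- nucleotide_diversity(env$panel, windows = feats,
                                   min_alleles = config$popgen$min_alleles)
    write_tsv_file(pi_tab, p("pi.tsv"))
    grps <- sort(unique(env$panel$groups))
    fst <- do.call(rbind, lapply(utils::combn(grps, 2, simplify = FALSE),
      function(gg) {
        r <- pairwise_fst(env$panel, gg[1], gg[2])
        data.frame(group_a = r$group_a, group_b = r$group_b, fst = r$fst,
                   n_sites = r$n_sites)
      }))
    write_tsv_file(fst, p("fst.tsv"))
    write_tsv_file(snp_density(env$panel, feats), p("density.tsv"))
    pi_group <- tapply(pi_tab$pi, pi_tab$group, mean)
    shifts <- diversity_shift(pi_group, default_lineage_edges())
    write_tsv_file(shifts, p("shifts.tsv"))
    list(features = nrow(feats), fst_pairs = nrow(fst))
  })

  run_stage("cerna", unname(inputs[c("binding_lnc", "binding_mrna", "expr")]),
            p(c("triangles.tsv", "nodes.tsv", "edges.tsv")),
            config$cerna, function() {
    shared <- shared_mirnas(read_tsv_file(inputs[["binding_lnc"]]),
                            read_tsv_file(inputs[["binding_mrna"]]),
                            expectation_max = config$cerna$expectation_max)
    tri <- build_triangles(shared, env$expr,
                           rho_min = config$cerna$rho_min,
                           alpha = config$cerna$alpha,
                           sign = config$cerna$sign)
    net <- network_export(tri, env$pairs)
    write_tsv_file(tri, p("triangles.tsv"))
    write_tsv_file(net$nodes, p("nodes.tsv"))
    write_tsv_file(net$edges, p("edges.tsv"))
    list(triangles = nrow(tri))
  })

  run_stage("assoc", unname(inputs[c("array", "array_positions", "pheno",
                                     "qtl", "introgression")]),
            p(c("gwas.tsv", "assoc_candidates.tsv", "coloc.tsv",
                "enrichment.tsv")), config$assoc, function() {
    geno <- read_expression(inputs[["array"]])
    positions <- read_tsv_file(inputs[["array_positions"]])
    pheno <- read_tsv_file(inputs[["pheno"]])
    traits <- setdiff(names(pheno), "sample")
    gwas <- do.call(rbind, lapply(traits, function(tr) {
      y <- setNames(pheno[[tr]], pheno$sample)
      h <- gwas_scan(geno, y, positions, n_pcs = config$assoc$n_pcs,
                     maf = config$assoc$maf, ne = config$assoc$ne)
      h$trait <- tr
      h
    }))
    write_tsv_file(gwas, p("gwas.tsv"))
    feats <- data.frame(feature_id = env$candidates$transcript_id,
                        chrom = env$candidates$chrom,
                        start = env$candidates$start,
                        end = env$candidates$end, stringsAsFactors = FALSE)
    cand <- assign_candidates(gwas, feats, window = config$assoc$window)
    write_tsv_file(cand, p("assoc_candidates.tsv"))
    qtl <- read_bed(inputs[["qtl"]])
    intro <- read_bed(inputs[["introgression"]])
    coloc <- rbind(cbind(set = "qtl", colocalize(feats, qtl)),
                   cbind(set = "introgression", colocalize(feats, intro)))
    write_tsv_file(coloc, p("coloc.tsv"))
    in_intro <- feats$feature_id %in%
      coloc$feature_id[coloc$set == "introgression"]
    paired <- feats$feature_id %in% env$pairs$lncrna_id
    enr <- fisher_enrichment(sum(in_intro & paired), sum(in_intro & !paired),
                             sum(!in_intro & paired), sum(!in_intro & !paired))
    write_tsv_file(data.frame(test = "introgression_x_pairs", p_value = enr),
                   p("enrichment.tsv"))
    list(hits = sum(gwas$passes_threshold), candidates = nrow(cand))
  })

  run_stage("conserve", unname(inputs[["homology"]]),
            p(c("conservation.tsv", "single_copy.txt", "species_tree.nwk")),
            config$conserve, function() {
    rec <- conservation_score(read_tsv_file(inputs[["homology"]]),
                              threshold = config$conserve$threshold,
                              formula = config$conserve$formula)
    write_tsv_file(rec, p("conservation.tsv"))
    sp <- sort(unique(rec$species))
    sc <- single_copy_set(rec, sp)
    writeLines(sc, p("single_copy.txt"))
    if (length(sc) >= 1 && length(sp) >= 2) {
      tr <- nj_tree(species_distances(rec, species = sp, queries = sc))
      write_newick(tr, p("species_tree.nwk"))
    }
    list(retained = sum(rec$retained), single_copy = length(sc))
  })

  flush_manifest()
  invisible(manifest)
}
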