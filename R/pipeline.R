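#' Configuration for an end-to-end phylogeography run
#'
#' Collects all inputs, constants, per-stage replicate numbers and seeds
#' for [run_all()]. With no input files, the run starts from a synthetic
#' study fixture generated under the configured refugial model.
#'
#' @param out_dir Output directory for the per-stage tables and manifest.
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @param fasta,meta Optional alignment + metadata paths; `NULL` generates
#'   the synthetic fixture instead.
#' @param spec [fixture_spec()] used for generation and for the constants
#'   (rate, L, g) of the dating stages.
#' @param hypotheses Refugial hypotheses to test (subset of `a`--`e`).
#' @param nreps_neutrality,nreps_mismatch,nreps_s,n_genealogies_rlr,n_perm_amova
#'   Replicate numbers per stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, fasta = NULL, meta = NULL,
                       spec = fixture_spec(), hypotheses = c("a", "e"),
                       nreps_neutrality = 1000L, nreps_mismatch = 1000L,
                       nreps_s = 1000L, n_genealogies_rlr = 500L,
                       n_perm_amova = 1000L) {
  stopifnot(all(hypotheses %in% c("a", "b", "c", "d", "e")))
  if (!is.null(fasta) && !file.exists(fasta)) stopf("missing input: %s", fasta)
  structure(list(out_dir = out_dir, seed = as.integer(seed), fasta = fasta,
                 meta = meta, spec = spec, hypotheses = hypotheses,
                 nreps_neutrality = nreps_neutrality,
                 nreps_mismatch = nreps_mismatch, nreps_s = nreps_s,
                 n_genealogies_rlr = n_genealogies_rlr,
                 n_perm_amova = n_perm_amova),
            class = "run_config")
}

#' Run the full phylogeography analysis
#'
#' Executes the stages in fixed order — data (load or generate), haplotype
#' collapsing, diversity table, neutrality tests and mismatch analyses per
#' lineage, AMOVA over the lineage grouping, S-statistic refugial-hypothesis
#' tests, and refugia localization per lineage — writing one tab-separated
#' table per stage plus a JSON manifest of seeds and versions. A stage
#' failure halts the run with a stage-tagged error; tables already written
#' are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seed + c(fixture = 101L, neutrality = 202L, mismatch = 303L,
                           amova = 404L, s_dist = 505L, rlr = 606L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  log_stage <- function(...) message(sprintf(...))
  tsv <- function(df, file, comment) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "w")
    writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  out <- list()

  log_stage("stage: data")
  fix <- stage("data", {
    if (is.null(config$fasta)) {
      generate_study_fixture(config$spec, seed = seeds[["fixture"]])
    } else {
      list(alignment = read_alignment(config$fasta, config$meta), tree = NULL)
    }
  })
  out$fixture <- fix

  log_stage("stage: haplotypes")
  ht <- stage("haplotypes", collapse_haplotypes(fix$alignment))
  d <- stage("haplotypes", pairwise_differences(ht))
  out$haplotypes <- ht

  log_stage("stage: diversity")
  div <- stage("diversity", {
    rbind(diversity_table(ht, d, by = "population"),
          diversity_table(ht, d, by = "lineage"))
  })
  tsv(div, "diversity.tsv", "per-population and per-lineage diversity indices")
  out$diversity <- div

  lineages <- unique(ht$lineages)
  big <- lineages[vapply(lineages, function(l) sum(scope_counts(ht, l)) >= 10,
                         logical(1L))]

  log_stage("stage: neutrality")
  neu <- stage("neutrality", {
    do.call(rbind, lapply(big, function(l) {
      cc <- scope_counts(ht, l)
      S <- count_segregating(ht$sequences[names(cc), , drop = FALSE])
      if (sum(cc) < 4 || S < 1) {
        # monomorphic or under-sampled scope: statistics undefined
        return(data.frame(lineage = l, n = sum(cc), S = S, D = NA_real_,
                          p_D = NA_real_, Fs = NA_real_, p_Fs = NA_real_))
      }
      r <- neutrality_test(ht, d, l, nreps = config$nreps_neutrality,
                           seed = seeds[["neutrality"]])
      data.frame(lineage = l, n = r$n, S = r$S_seg, D = r$D, p_D = r$p_D,
                 Fs = r$Fs, p_Fs = r$p_Fs)
    }))
  })
  tsv(neu, "neutrality.tsv", "Tajima's D and Fu's Fs with simulated p-values")
  out$neutrality <- neu

  log_stage("stage: mismatch")
  mm <- stage("mismatch", {
    do.call(rbind, lapply(big, function(l) {
      r <- mismatch_test(ht, d, l, rate = config$spec$rate, L = config$spec$L,
                         nreps = config$nreps_mismatch, seed = seeds[["mismatch"]])
      data.frame(lineage = l, tau = r$tau, SSD = r$SSD, p_SSD = r$p_SSD,
                 raggedness = r$raggedness, p_rag = r$p_rag,
                 expansion_time_My = r$t_years / 1e6)
    }))
  })
  tsv(mm, "mismatch.tsv", "sudden-expansion fits and expansion-time dating")
  out$mismatch <- mm

  log_stage("stage: amova")
  grouping <- stats::setNames(ht$lineages, colnames(ht$counts))
  am <- stage("amova", amova(ht, d, grouping, n_perm = config$n_perm_amova,
                             seed = seeds[["amova"]]))
  tsv(data.frame(phi_st = am$phi_st, phi_sc = am$phi_sc, phi_ct = am$phi_ct,
                 p_st = am$p_phi_st, p_sc = am$p_phi_sc, p_ct = am$p_phi_ct,
                 pct_among_groups = am$percent[1L],
                 pct_among_pops = am$percent[2L],
                 pct_within = am$percent[3L]),
      "amova.tsv", "AMOVA over the lineage grouping")
  out$amova <- am

  log_stage("stage: refugia tests")
  pops <- config$spec$pops
  s_obs <- if (!is.null(fix$tree)) {
    lin_states <- stats::setNames(pops$lineage, pops$population_id)
    s_statistic(fix$tree, lin_states[tip_populations(fix$tree)])
  } else NA_integer_
  ref <- stage("refugia", {
    do.call(rbind, lapply(config$hypotheses, function(h) {
      model <- refugia_model(h, config$spec$overall_Ne, pops,
                             apportion = config$spec$apportion, g = config$spec$g)
      sd <- simulate_s_distribution(model, nreps = config$nreps_s,
                                    seed = seeds[["s_dist"]])
      dec <- if (!is.na(s_obs)) refugia_test(s_obs, sd) else
        list(reject = NA, lo95 = sd$lo95, hi95 = sd$hi95)
      data.frame(hypothesis = h, S_obs = s_obs, lo95 = dec$lo95,
                 hi95 = dec$hi95, reject = dec$reject)
    }))
  })
  tsv(ref, "refugia_tests.tsv", "S-statistic refugial-hypothesis decisions")
  out$refugia <- ref

  log_stage("stage: refugia localization")
  rlr <- stage("rlr", {
    model <- refugia_model(config$spec$hypothesis, config$spec$overall_Ne,
                           pops, apportion = config$spec$apportion,
                           g = config$spec$g)
    do.call(rbind, lapply(big, function(l) {
      keep <- pops$population_id[pops$lineage == l]
      trees <- with_seed(seeds[["rlr"]], {
        lapply(seq_len(config$n_genealogies_rlr), function(i) {
          tr <- sim_gene_tree_impl(model)
          ape::keep.tip(tr, tr$tip.label[tip_populations(tr) %in% keep])
        })
      })
      res <- rlr_root_probabilities(trees, stats::setNames(
        tip_populations(trees[[1L]]), trees[[1L]]$tip.label))
      data.frame(lineage = l, locality = names(res$scores),
                 mrca_prob = as.numeric(res$scores))
    }))
  })
  tsv(rlr, "rlr.tsv", "root-origin (MRCA) probabilities per lineage")
  out$rlr <- rlr

  manifest <- list(package_version = as.character(utils::packageVersion("refugia")),
                   r_version = R.version.string,
                   master_seed = config$seed, stage_seeds = as.list(seeds),
                   hypotheses = config$hypotheses,
                   constants = list(rate = config$spec$rate, L = config$spec$L,
                                    g = config$spec$g,
                                    overall_Ne = config$spec$overall_Ne))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
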