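#' Run the end-to-end synthetic-study pipeline
#'
#' Orchestrates the analysis stages in dependency order over a synthetic
#' study: simulate -> popgen summaries -> windowed tree statistics and
#' pseudo-likelihood species tree -> SFS model comparison -> ABC model
#' choice. Every artifact written is recorded in a manifest with its MD5
#' checksum, so reruns with the same configuration and seed can be verified
#' for reproducibility. The numbered scripts under `analysis/` are thin
#' drivers over this same machinery.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{stages}{character subset of `c("simulate", "popgen",
#'       "treestats", "mscfit", "sfsfit", "abc")`.}
#'     \item{out}{output directory.}
#'     \item{seed}{master seed (required when any stochastic stage runs).}
#'     \item{model}{generating model index (default 1).}
#'     \item{n_loci, locus_length, haplotypes_per_species}{study design
#'       (defaults 100, 2000, 8).}
#'     \item{sfs_windows, sfs_n_per}{SFS stage settings (defaults 5000, 8).}
#'     \item{abc_n_sims, abc_tolerance}{ABC stage settings (defaults 150
#'       rows/model, 0.05).}
#'   }
#' @return data.frame manifest (file, md5), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  known <- c("simulate", "popgen", "treestats", "mscfit", "sfsfit", "abc")
  if (!all(stages %in% known))
    stop("unknown stage: ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  model <- cfg("model", 1)
  files <- character(0)
  study <- NULL

  if ("simulate" %in% stages) {
    dem <- candidate_demographies(model, outgroups = TRUE)
    design <- sample_design(haplotypes_per_species = cfg("haplotypes_per_species", 8),
                            n_loci = cfg("n_loci", 100),
                            locus_length = cfg("locus_length", 2000),
                            include_outgroups = TRUE, seed = config$seed)
    study <- emit_study(dem, design, out_dir = file.path(out, "study"))
    files <- c(files, file.path(out, "study",
                                c("trees.nwk", "variants.tsv", "species_map.tsv")))
  }

  need_study <- function(stage) {
    if (is.null(study))
      stop("dependency error: stage '", stage,
           "' needs the simulate stage (no study inputs present)")
  }

  if ("popgen" %in% stages) {
    need_study("popgen")
    sm <- stats::setNames(study$species_map$species, study$species_map$haplotype)
    sp <- study$truth$species
    genos <- study_locus_genos(study)
    # per-species diversity table
    div <- do.call(rbind, lapply(sp, function(s) {
      haps <- names(sm)[sm == s]
      g <- do.call(rbind, lapply(genos, function(m) m[, haps, drop = FALSE]))
      d <- diversity(g, L = length(genos) * study$design$locus_length)
      data.frame(species = s, n_haplotypes = length(haps),
                 S = d$S, pi = d$pi, theta_w = d$theta_w)
    }))
    utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    geno_all <- do.call(rbind, genos)
    shar <- allele_sharing(geno_all, sm, sp)
    utils::write.table(data.frame(cell = names(shar$cells),
                                  count = as.integer(shar$cells)),
                       file.path(out, "allele_sharing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sv <- summary_vector(study)
    utils::write.table(data.frame(stat = names(sv), value = unname(sv)),
                       file.path(out, "summary_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(out, c("diversity.tsv", "allele_sharing.tsv",
                                       "summary_stats.tsv")))
  }

  if ("treestats" %in% stages) {
    need_study("treestats")
    sm <- stats::setNames(study$species_map$species, study$species_map$haplotype)
    n <- length(study$genealogies)
    windows <- data.frame(chrom = "sim",
                          start = (seq_len(n) - 1) * study$design$locus_spacing,
                          end = (seq_len(n) - 1) * study$design$locus_spacing +
                            study$design$locus_length)
    scan <- window_scan(windows, study$genealogies, sm,
                        ingroup = study$truth$species,
                        outgroups = study$truth$outgroups$label,
                        n_rounds = cfg("n_rounds", 50), seed = config$seed)
    utils::write.table(scan$windows, file.path(out, "window_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(windows, scan$spectra),
                       file.path(out, "window_spectra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(out, c("window_stats.tsv",
                                       "window_spectra.tsv")))
    config$.spectra <- scan$spectra
  }

  if ("mscfit" %in% stages) {
    need_study("mscfit")
    sm <- stats::setNames(study$species_map$species, study$species_map$haplotype)
    keys <- vapply(study$genealogies, function(tr) {
      tryCatch(subsampled_key(tr,
                              pick_one_per_species(tr, sm,
                                                   c(study$truth$species,
                                                     study$truth$outgroups$label)),
                              sm, study$truth$species,
                              study$truth$outgroups$label),
               quartetcoal_polytomy = function(e) NA_character_)
    }, "")
    fit <- fit_species_tree(keys[!is.na(keys)], study$truth$species)
    jsonlite::write_json(list(best = fit$key,
                              branch_lengths = fit$branch_lengths,
                              logL = fit$logL, ties = fit$ties,
                              scores = as.list(fit$scores)),
                         file.path(out, "species_tree_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out, "species_tree_fit.json"))
  }

  if ("sfsfit" %in% stages) {
    dem_true <- candidate_demographies(model)
    obs <- simulate_sfs_counts(dem_true, n_per_species = cfg("sfs_n_per", 8),
                               n_windows = cfg("sfs_windows", 5000),
                               seed = config$seed)
    fits <- lapply(1:4, function(m)
      fit_model(m, obs, n_runs = cfg("sfs_runs", 1), seed = config$seed,
                n_sims = cfg("sfs_sims", 300), maxit = cfg("sfs_maxit", 60)))
    cmp <- compare_models(fits)
    utils::write.table(cmp, file.path(out, "sfs_model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(out, "sfs_model_comparison.tsv"))
  }

  if ("abc" %in% stages) {
    acfg <- abc_config(n_sims = cfg("abc_n_sims", 150),
                       tolerance = cfg("abc_tolerance", 0.05),
                       n_loci = cfg("abc_n_loci", 60),
                       locus_length = cfg("abc_locus_length", 1000),
                       haplotypes_per_species = cfg("haplotypes_per_species", 8),
                       seed = config$seed)
    tables <- lapply(1:4, simulate_reference_table, config = acfg)
    dem_true <- candidate_demographies(model)
    design <- sample_design(haplotypes_per_species = acfg$haplotypes_per_species,
                            n_loci = acfg$n_loci,
                            locus_length = acfg$locus_length,
                            seed = derive_seed(config$seed, 31L))
    observed <- simulate_summary_vector(dem_true, design)
    pp <- model_posterior(tables, observed, tolerance = acfg$tolerance)
    jsonlite::write_json(list(posterior = as.list(pp),
                              method = attr(pp, "method")),
                         file.path(out, "abc_model_choice.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out, "abc_model_choice.json"))
  }

  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# deterministic first leaf per species (used by the pipeline's mscfit stage:
# one haplotype per species, no random subsampling)
pick_one_per_species <- function(tree, species_map, species) {
  sp <- species_map[tree$tip.label]
  vapply(species, function(s) tree$tip.label[sp == s][1], "")
}
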