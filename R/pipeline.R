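# Config-driven orchestration: seqcore -> diversity -> amova -> demography
# -> network -> (msat) -> spatial, with CSV reports and a run log.

#' Read a pipeline configuration
#'
#' JSON with fields: `markers` (array of {name, fasta, mu_pct_per_myr}),
#' `population_table` (path), optional `geo_km` (CSV matrix path), optional
#' `bands` (band-phenotype table path), `t_gen` (years), `n_perm`, `seed`,
#' `out_dir`.  Seeds and permutation counts must be explicit.
#'
#' @param path JSON file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("markers", "population_table", "t_gen", "n_perm", "seed",
              "out_dir")) {
    if (is.null(cfg[[f]])) stop("config missing field: ", f)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes sequence summarisation, diversity, AMOVA, mismatch/expansion
#' dating, Fu's Fs, haplotype network, optional band-based microsatellite
#' analysis and optional isolation-by-distance, writing CSV/GraphML/newick
#' outputs and a run log into `out_dir`.  All randomness derives from the
#' config seed, so reruns are byte-identical.
#'
#' @param config a config list or path to a JSON config
#'   ([read_pipeline_config]).
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("fishpopgen pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("fishpopgen"))),
                 paste0("r_version: ", R.version.string),
                 paste0("seed: ", config$seed),
                 paste0("n_perm: ", config$n_perm),
                 paste0("t_gen: ", config$t_gen))
  results <- list()
  markers <- config$markers
  if (is.data.frame(markers)) {
    markers <- lapply(seq_len(nrow(markers)), function(i) as.list(markers[i, ]))
  }
  alns <- list()
  pm <- NULL
  for (mk in markers) {
    rd <- read_fasta_alignment(mk$fasta, config$population_table)
    alns[[mk$name]] <- rd$alignment
    pm <- rd$pop_map
    log_lines <- c(log_lines, sprintf("marker %s: %d sequences x %d sites (mu=%s %%/site/Myr)",
                                      mk$name, length(rd$alignment$ids),
                                      n_sites(rd$alignment), mk$mu_pct_per_myr))
  }
  if (length(alns) > 1) {
    conc <- Reduce(concatenate_alignments, alns)
    mu_conc <- config$concatenated_mu_pct_per_myr
    if (is.null(mu_conc)) {
      # length-weighted average when not supplied
      ks <- vapply(alns, n_sites, 0)
      mus <- vapply(markers, function(m) m$mu_pct_per_myr, 0)
      mu_conc <- sum(mus * ks) / sum(ks)
    }
    alns[["concatenated"]] <- conc
    markers <- c(markers, list(list(name = "concatenated",
                                    mu_pct_per_myr = mu_conc)))
  }
  mu_of <- setNames(vapply(markers, function(m) m$mu_pct_per_myr, 0),
                    vapply(markers, function(m) m$name, ""))
  for (nm in names(alns)) {
    aln <- alns[[nm]]
    ss <- classify_sites(aln)
    write.csv(data.frame(t(attr(ss, "counts"))),
              file.path(out, paste0(nm, "_sites.csv")), row.names = FALSE)
    div <- nucleotide_diversity(aln, pm)
    write.csv(div, file.path(out, paste0(nm, "_diversity.csv")),
              row.names = FALSE)
    ht <- collapse_haplotypes(aln, pm)
    export_haplotypes(ht, fasta_path = file.path(out, paste0(nm, "_haplotypes.fasta")),
                      csv_path = file.path(out, paste0(nm, "_haplotype_counts.csv")))
    D <- pairwise_differences(aln)
    am <- amova(D, pm, n_perm = config$n_perm, seed = config$seed)
    write_amova_csv(am, file.path(out, paste0(nm, "_amova.csv")))
    # per-region demography + overall
    groups <- c(list(all = aln$ids), split(pm$id, pm$region))
    dem_rows <- list()
    for (g in names(groups)) {
      ids <- groups[[g]]
      if (length(ids) < 3) next
      sub <- subset_alignment(aln, ids)
      obs <- mismatch_observed(sub)
      fit <- fit_sudden_expansion(obs)
      fs <- fus_fs(sub, B = max(config$n_perm %/% 10, 100),
                   seed = config$seed)
      et <- expansion_time(fit$tau, mu_of[[nm]], n_sites(aln), config$t_gen)
      dem_rows[[g]] <- data.frame(
        group = g, tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
        SSD = fit$ssd, raggedness = fit$raggedness,
        Fs = fs$Fs, Fs_P = fs$P,
        T_ma = round(et$T_ma, 3), stringsAsFactors = FALSE)
      obs_df <- data.frame(differences = 0:obs$d_max, observed = obs$freq,
                           expected = fit$expected)
      write.csv(obs_df, file.path(out, sprintf("%s_mismatch_%s.csv", nm, g)),
                row.names = FALSE)
    }
    write.csv(do.call(rbind, dem_rows),
              file.path(out, paste0(nm, "_demography.csv")), row.names = FALSE)
    # network
    if (length(ht$sequences) >= 2) {
      net <- median_joining(ht)
      export_network(net, file.path(out, paste0(nm, "_network.graphml")),
                     "graphml")
      write.csv(net$edges, file.path(out, paste0(nm, "_network_edges.csv")),
                row.names = FALSE)
    }
    # NJ tree on haplotype K2P distances
    if (length(ht$sequences) >= 3) {
      hap_aln <- dna_alignment(ht$sequences)
      tr <- try(build_nj_tree(k2p_matrix(hap_aln)), silent = TRUE)
      if (!inherits(tr, "try-error")) {
        ape::write.tree(tr, file.path(out, paste0(nm, "_nj.nwk")))
      }
    }
    results[[nm]] <- list(amova = am, demography = dem_rows)
  }
  # microsatellites
  if (!is.null(config$bands)) {
    bpm <- read_band_phenotypes(config$bands)
    bb <- phenotypes_to_binary(bpm)
    # attach regions from the sequence population map when populations match
    if (!is.null(config$band_population_table)) {
      bb$pop_map <- as_pop_map(config$band_population_table)
    }
    div <- band_diversity(bb)
    write.csv(div, file.path(out, "msat_diversity.csv"), row.names = FALSE)
    fst <- binary_fst(bb, n_perm = config$n_perm, seed = config$seed)
    write_amova_csv(fst$amova, file.path(out, "msat_amova.csv"))
    write.csv(fst$pairwise$phi_st, file.path(out, "msat_pairwise_fst.csv"))
    nei <- nei_unbiased_distance(bb)
    write.csv(nei$D, file.path(out, "msat_nei_distance.csv"))
    pc <- pcoa(sqrt(binary_squared_distances(bb$binary)))
    write.csv(pc$coordinates, file.path(out, "msat_pcoa.csv"))
    results$msat <- list(diversity = div, fst = fst, nei = nei)
  }
  # isolation by distance
  if (!is.null(config$geo_km)) {
    geo <- as.matrix(read.csv(config$geo_km, row.names = 1, check.names = FALSE))
    nm_main <- names(alns)[length(alns)]
    D <- pairwise_differences(alns[[nm_main]])
    pw <- pairwise_phi_st(D, pm, n_perm = 0)
    phi <- pw$phi_st[rownames(geo), rownames(geo)]
    ibd <- mantel_ibd(phi, geo, n_perm = config$n_perm, seed = config$seed)
    write.csv(data.frame(R = ibd$R, P = ibd$P, n_perm = ibd$n_perm,
                         n_pops = ibd$n_pops),
              file.path(out, "ibd.csv"), row.names = FALSE)
    results$ibd <- ibd
  }
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(results)
}
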