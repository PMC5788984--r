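#' Read a pipeline run configuration
#'
#' YAML file with input paths, missing-data policy, partition definitions,
#' rarefaction / demography / ABC settings and the output directory. Any
#' omitted setting falls back to the documented default.
#'
#' @param path Path to a YAML file (or a pre-built list).
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    input_fasta = NULL,
    samples = NULL,
    policy = "complete_deletion",
    partition = "group",
    lineage = NULL,
    seed = 1L,
    rarefaction = list(reps = 5, target_n = NULL),
    demography = list(n_boot = 100, p_reps = 1000),
    abc = list(
      scenarios = c("gradual_north_derived", "gradual_south_derived",
                    "sudden_trifurcation"),
      populations = c("P1", "P2", "P3"),
      n_sims = 1000, acceptance = 0.01, generation_time = 10,
      sample_sizes = c(25, 25, 25), L = 866
    ),
    network = list(limit = NULL),
    output_dir = "pipeline_out"
  )
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("reps")) if (cfg$rarefaction[[f]] <= 0) abort("Rarefaction reps must be positive.")
  if (cfg$demography$n_boot <= 0) abort("n_boot must be positive.")
  structure(cfg, class = c("run_config", "list"))
}

load_inputs <- function(cfg) {
  if (is.null(cfg$input_fasta) || is.null(cfg$samples)) {
    abort("Config needs input_fasta and samples paths for this stage.")
  }
  a <- read_alignment(cfg$input_fasta)
  s <- read_sample_table(cfg$samples)
  if (!is.null(cfg$lineage)) s <- s[s$lineage %in% cfg$lineage, , drop = FALSE]
  list(a = a, s = s)
}

write_manifest <- function(cfg, stage, out_dir, artifacts, t0) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("refugia")),
    seed = cfg$seed,
    elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
    inputs = Filter(Negate(is.null), list(
      input_fasta = cfg$input_fasta, samples = cfg$samples
    )),
    input_md5 = {
      paths <- unlist(Filter(function(p) !is.null(p) && file.exists(p),
                             list(cfg$input_fasta, cfg$samples)))
      if (length(paths)) as.list(Filter(Negate(is.na), tools::md5sum(paths)))
      else list()
    },
    artifacts = artifacts
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Stages: `haplotypes` (collapse + TSV), `network` (minimum-spanning
#' network, GraphML + edge list + lineage separations), `diversity`
#' (per-group indices, total and rarefied), `demography` (mismatch fit,
#' bootstrap goodness of fit, neutrality tests per group), `abc` (reference
#' table, scenario choice, parameter estimation), `simulate` (one scenario
#' draw to FASTA/TSV), `fixtures` (the three synthetic lineage fixtures).
#' Every stage writes its artifacts plus a JSON run manifest (package
#' version, seed, input digests, timing) into the output directory.
#'
#' @param stage Stage name.
#' @param config A config list, path to YAML, or [read_run_config()] result.
#' @param ... Config overrides (e.g. `seed = 7`, `output_dir = "out"`).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(stage = c("haplotypes", "network", "diversity",
                                   "demography", "abc", "simulate", "fixtures"),
                         config = list(), ...) {
  stage <- match.arg(stage)
  cfg <- read_run_config(config)
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  artifacts <- switch(
    stage,
    haplotypes = stage_haplotypes(cfg, out_dir),
    network = stage_network(cfg, out_dir),
    diversity = stage_diversity(cfg, out_dir),
    demography = stage_demography(cfg, out_dir),
    abc = stage_abc(cfg, out_dir),
    simulate = stage_simulate(cfg, out_dir),
    fixtures = stage_fixtures(cfg, out_dir)
  )
  artifacts$manifest <- write_manifest(cfg, stage, out_dir, artifacts, t0)
  invisible(artifacts)
}

stage_haplotypes <- function(cfg, out_dir) {
  io <- load_inputs(cfg)
  ht <- collapse_haplotypes(io$a, io$s, policy = cfg$policy,
                            group_col = cfg$partition)
  p <- file.path(out_dir, "haplotypes.tsv")
  write_haplotype_table(ht, p)
  list(haplotypes = p)
}

stage_network <- function(cfg, out_dir) {
  io <- load_inputs(cfg)
  ht <- collapse_haplotypes(io$a, io$s, policy = cfg$policy,
                            group_col = cfg$partition)
  d <- pairwise_diff_matrix(ht, policy = cfg$policy)
  net <- build_network(d, ht, limit = cfg$network$limit)
  pg <- file.path(out_dir, "network.graphml")
  pe <- file.path(out_dir, "network_edges.tsv")
  write_network(net, pg, "graphml")
  write_network(net, pe, "edges")
  # pairwise lineage separations (minimum mutation steps)
  lht <- collapse_haplotypes(io$a, io$s, policy = cfg$policy, group_col = "lineage")
  lin <- attr(lht, "groups")
  seps <- NULL
  if (length(lin) >= 2) {
    dl <- pairwise_diff_matrix(lht, policy = cfg$policy)
    fr <- as_tibble(lht)
    combs <- utils::combn(lin, 2)
    seps <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
      A <- which(fr[[combs[1, i]]] > 0 & fr[[combs[2, i]]] == 0)
      B <- which(fr[[combs[2, i]]] > 0 & fr[[combs[1, i]]] == 0)
      tibble(lineage_a = combs[1, i], lineage_b = combs[2, i],
             min_steps = if (length(A) && length(B)) min_steps_between(dl, A, B) else 0L)
    })
    ps <- file.path(out_dir, "lineage_separations.tsv")
    readr::write_tsv(seps, ps)
  }
  c(list(graphml = pg, edges = pe),
    if (!is.null(seps)) list(separations = file.path(out_dir, "lineage_separations.tsv")))
}

stage_diversity <- function(cfg, out_dir) {
  io <- load_inputs(cfg)
  prof <- diversity_profile(io$a, io$s, partition = cfg$partition)
  sizes <- table(io$s[[cfg$partition]])
  target <- cfg$rarefaction$target_n %||% min(sizes)
  seeds <- spawn_seeds(cfg$seed, length(sizes))
  rare <- purrr::map_dfr(which(sizes > target), function(i) {
    g <- names(sizes)[i]
    r <- rarefy(io$a, io$s, g, target_n = target, reps = cfg$rarefaction$reps,
                seed = seeds[i], partition = cfg$partition)
    dplyr::mutate(r, group = paste0(g, " (rarefied)"))
  })
  full <- dplyr::bind_rows(prof, rare)
  pt <- file.path(out_dir, "diversity.tsv")
  pj <- file.path(out_dir, "diversity.json")
  readr::write_tsv(format_diversity_table(full), pt)
  jsonlite::write_json(full, pj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  list(diversity_tsv = pt, diversity_json = pj)
}

stage_demography <- function(cfg, out_dir) {
  io <- load_inputs(cfg)
  groups <- unique(io$s[[cfg$partition]])
  seeds <- spawn_seeds(cfg$seed, 2 * length(groups))
  rows <- purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[i]
    ids <- io$s$sample_id[io$s[[cfg$partition]] == g]
    ids <- intersect(ids, rownames(io$a))
    if (length(ids) < 4) {
      return(tibble(group = g, n = length(ids)))
    }
    sub <- io$a[ids, , drop = FALSE]
    h <- mismatch_histogram(sub, policy = cfg$policy)
    fit <- fit_sudden_expansion(h)
    gof <- expansion_gof(sub, fit, n_boot = cfg$demography$n_boot, seed = seeds[2 * i - 1])
    nt <- neutrality_tests(sub, n_reps = cfg$demography$p_reps, seed = seeds[2 * i])
    dplyr::bind_cols(
      tibble(group = g), nt,
      tibble(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
             modality = h$modality),
      gof
    )
  })
  p <- file.path(out_dir, "demography.tsv")
  readr::write_tsv(rows, p)
  list(demography = p)
}

stage_abc <- function(cfg, out_dir) {
  io <- load_inputs(cfg)
  ab <- cfg$abc
  seeds <- spawn_seeds(cfg$seed, 2)
  obs <- summary_statistics(io$a, io$s, partition = cfg$partition,
                            group_order = ab$populations)
  ref <- build_reference_table(
    kinds = ab$scenarios, spec = prior_spec(),
    n_sims = ab$n_sims, sample_sizes = ab$sample_sizes,
    populations = ab$populations, L = ab$L, seed = seeds[1]
  )
  n_closest <- max(2, ceiling(ab$acceptance * nrow(ref)))
  if (n_closest < 30) {
    warn(paste0("Only ", n_closest, " accepted rows; posterior probabilities ",
                "will be unstable. Increase n_sims or acceptance."))
  }
  mc <- model_choice(obs, ref, n_closest = n_closest)
  est <- estimate_parameters(ref, obs, scenario_id = mc$selected,
                             n_closest = min(n_closest,
                                             sum(ref$scenario == mc$selected)),
                             g = ab$generation_time)
  pr <- file.path(out_dir, "abc_reference_table.tsv")
  pj <- file.path(out_dir, "abc_report.json")
  readr::write_tsv(ref, pr)
  jsonlite::write_json(
    list(observed = obs, posterior = mc$posterior,
         selected = mc$selected, selected_kind = mc$selected_kind,
         n_closest = n_closest, parameters = est,
         priors = unclass(prior_spec()), seed = cfg$seed),
    pj, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  list(reference_table = pr, report = pj)
}

stage_simulate <- function(cfg, out_dir) {
  ab <- cfg$abc
  spec <- prior_spec()
  pars <- sample_priors(spec, ab$scenarios[1], n = 1, seed = cfg$seed)
  sim <- make_pseudoobs(ab$scenarios[1], as.list(pars), ab$sample_sizes,
                        ab$populations, ab$L, seed = cfg$seed)
  pf <- file.path(out_dir, "simulated.fasta")
  ps <- file.path(out_dir, "simulated_samples.tsv")
  pt <- file.path(out_dir, "simulated_truth.json")
  write_alignment(sim$alignment, pf)
  write_sample_table(sim$samples, ps)
  jsonlite::write_json(sim$truth, pt, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(fasta = pf, samples = ps, truth = pt)
}

stage_fixtures <- function(cfg, out_dir) {
  seeds <- spawn_seeds(cfg$seed, 3)
  fixtures <- list(
    blue = make_star_expansion(seed = seeds[1]),
    yellow = make_two_refuge(seed = seeds[2]),
    red = make_bimodal_pair(seed = seeds[3])
  )
  out <- list()
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    pf <- file.path(out_dir, paste0(nm, ".fasta"))
    ps <- file.path(out_dir, paste0(nm, "_samples.tsv"))
    pt <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_alignment(fx$alignment, pf)
    write_sample_table(fx$samples, ps)
    truth <- fx$truth
    truth$subcluster <- NULL  # named vectors don't round-trip compactly
    jsonlite::write_json(truth, pt, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out[[paste0(nm, "_fasta")]] <- pf
    out[[paste0(nm, "_samples")]] <- ps
    out[[paste0(nm, "_truth")]] <- pt
  }
  out
}
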