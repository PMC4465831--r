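# End-to-end pipeline orchestration: synthesize -> interface analytics;
# simulate-umbrella -> wham -> dg; coop/audit on an affinity table.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages with defaults anchored to
#' the published protocol: contact cutoff 4.5 A, recurrence threshold 0.5
#' (more than 50\% of frames), network persistence 0.75, temperature 300 K,
#' WHAM bin width 0.01 A and tolerance 1e-6 kT, bound/unbound thresholds
#' 3.1-4.3 A in 0.2 A steps with upper integration limit 5.5 A.
#'
#' @param seed RNG seed governing every stochastic stage.
#' @param output_dir Where artifacts are written (`NULL`: nothing written).
#' @param toy_spec A [toy_complex_spec()] for the synthetic complex stages.
#' @param n_frames Frames of the synthetic unbiased ensemble.
#' @param pmf A [reference_pmf()] for the umbrella stage.
#' @param umbrella_windows Tibble (`center`, `k`) of umbrella windows.
#' @param bd A [bd_params()] for the Brownian umbrella sampler.
#' @param affinity An [affinity_table()] for the coop/audit stages
#'   (default: the packaged table, [utf1_affinity_table()]).
#' @param contact_cutoff,recurrence,persistence Contact analytics settings.
#' @param temperature Kelvin.
#' @param wham_bin_width,wham_tol WHAM settings.
#' @param thresholds,upper Bound/unbound thresholds and upper limit, A.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, output_dir = NULL,
                            toy_spec = NULL, n_frames = 400L,
                            pmf = pmf_double_well(),
                            umbrella_windows = NULL,
                            bd = NULL, affinity = NULL,
                            contact_cutoff = 4.5, recurrence = 0.5,
                            persistence = 0.75, temperature = 300,
                            wham_bin_width = 0.01, wham_tol = 1e-6,
                            thresholds = seq(3.1, 4.3, by = 0.2),
                            upper = 5.5) {
  if (is.null(toy_spec))
    toy_spec <- toy_complex_spec(
      n_basepairs = 12, n_protein_res = 4,
      contacts = tibble::tibble(protein_res = c(1, 2, 3, 4),
                                dna_level = c(3, 5, 8, 10),
                                dna_part = c("backbone", "base",
                                             "backbone", "base"),
                                persistence = c(0.9, 0.85, 0.95, 0.4)),
      seed = seed)
  if (is.null(umbrella_windows))
    umbrella_windows <- tibble::tibble(
      center = seq(2.6, 5.4, length.out = 20), k = 15)
  if (is.null(bd))
    bd <- bd_params(temperature = temperature, n_steps = 2e5,
                    save_stride = 10L, seed = seed)
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 toy_spec = toy_spec, n_frames = as.integer(n_frames),
                 pmf = pmf, umbrella_windows = umbrella_windows, bd = bd,
                 affinity = affinity, contact_cutoff = contact_cutoff,
                 recurrence = recurrence, persistence = persistence,
                 temperature = temperature,
                 wham_bin_width = wham_bin_width, wham_tol = wham_tol,
                 thresholds = thresholds, upper = upper),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate-complex", "contacts", "angles", "grooves",
                     "network", "simulate-umbrella", "wham", "dg", "coop",
                     "audit")

pipeline_deps <- list(
  "contacts" = "simulate-complex", "angles" = "simulate-complex",
  "grooves" = "simulate-complex", "network" = "simulate-complex",
  "wham" = "simulate-umbrella", "dg" = "wham")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate-complex` -> `contacts`/`angles`/`grooves`/`network`;
#' `simulate-umbrella` -> `wham` -> `dg`; `coop`/`audit` on the affinity
#' table). All randomness is governed by the config seed, so re-running with
#' an identical config reproduces every numeric output. When
#' `config$output_dir` is set, artifacts are written as TSV/JSON together
#' with the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of `simulate-complex`, `contacts`,
#'   `angles`, `grooves`, `network`, `simulate-umbrella`, `wham`, `dg`,
#'   `coop`, `audit` (default: all).
#' @return A named list of stage results, invisibly augmented with the paths
#'   written (attribute `files`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = PIPELINE_STAGES) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(PIPELINE_STAGES, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  for (s in stages) {
    dep <- pipeline_deps[[s]]
    if (!is.null(dep) && !dep %in% stages)
      stop("stage '", s, "' requires stage '", dep, "'")
  }
  out <- list()
  files <- character()
  dir <- config$output_dir
  save_tsv <- function(x, name) {
    if (is.null(dir)) return(invisible())
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(x), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfgp <- file.path(dir, "config.json")
    writeLines(jsonlite::toJSON(list(
      seed = config$seed, n_frames = config$n_frames,
      contact_cutoff = config$contact_cutoff,
      recurrence = config$recurrence, persistence = config$persistence,
      temperature = config$temperature,
      wham_bin_width = config$wham_bin_width, wham_tol = config$wham_tol,
      thresholds = config$thresholds, upper = config$upper,
      umbrella_windows = config$umbrella_windows,
      bd = unclass(config$bd)), auto_unbox = TRUE, digits = NA), cfgp)
    files <- c(files, cfgp)
  }

  dna_region <- region("dna", chains = c("A", "B"))
  prot_region <- region("protein", chains = "P")

  for (s in stages) {
    if (s == "simulate-complex") {
      out$ensemble <- gen_toy_complex_ensemble(config$toy_spec,
                                               config$n_frames)
    } else if (s == "contacts") {
      out$contacts <- contact_map(out$ensemble, prot_region, dna_region,
                                  cutoff = config$contact_cutoff,
                                  threshold = config$recurrence)
      save_tsv(out$contacts, "contacts")
      out$per_residue <- per_residue_profile(out$contacts)
      save_tsv(out$per_residue, "per_residue_contacts")
    } else if (s == "angles") {
      out$orientation <- rock_tumble(out$ensemble, dna_region, prot_region)
      save_tsv(out$orientation, "rock_tumble")
    } else if (s == "grooves") {
      out$grooves <- groove_widths(out$ensemble, dna_region)
      save_tsv(out$grooves$summary, "groove_widths")
      out$bend <- bend_profile(out$ensemble, dna_region)
      save_tsv(out$bend$summary, "bend_profile")
    } else if (s == "network") {
      sup <- superpose(out$ensemble, dna_region)
      nodes <- network_nodes(sup)
      corr <- cross_correlation(sup, nodes)
      out$network <- build_network(sup, nodes, corr,
                                   persistence = config$persistence,
                                   cutoff = config$contact_cutoff)
      save_tsv(out$network$edges, "network_edges")
    } else if (s == "simulate-umbrella") {
      out$umbrella <- gen_bd_umbrella(config$pmf, config$umbrella_windows,
                                      bd = config$bd)
      if (!is.null(dir)) {
        write_umbrella_text(out$umbrella, file.path(dir, "umbrella"))
        files <- c(files, file.path(dir, "umbrella", "manifest.tsv"))
      }
    } else if (s == "wham") {
      out$fe_profile <- wham(out$umbrella,
                             bin_width = config$wham_bin_width,
                             tol = config$wham_tol)
      save_tsv(out$fe_profile$profile, "fe_profile")
      out$theta <- theta_consistency(out$umbrella)
      save_tsv(out$theta, "theta_consistency")
    } else if (s == "dg") {
      ths <- config$thresholds
      sup <- range(out$fe_profile$profile$d[
        is.finite(out$fe_profile$profile$G)])
      ths <- ths[ths > sup[1] & ths < sup[2]]
      out$affinity_estimates <- threshold_sweep(
        out$fe_profile, thermo = thermo(config$temperature),
        thresholds = ths, upper = min(config$upper, sup[2]))
      save_tsv(out$affinity_estimates, "affinity_estimates")
    } else if (s == "coop") {
      tab <- config$affinity %||% utf1_affinity_table()
      out$cooperativity <- cooperativity(tab)
      out$domain_deltas <- domain_deltas(tab)
      save_tsv(out$cooperativity, "cooperativity")
      save_tsv(out$domain_deltas, "domain_deltas")
    } else if (s == "audit") {
      tab <- config$affinity %||% utf1_affinity_table()
      out$audit <- table_audit(tab)
      save_tsv(out$audit, "table_audit")
    }
  }
  attr(out, "files") <- files
  invisible(out)
}
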