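#' Default pipeline configuration
#'
#' All stage toggles and every physical constant used anywhere in the
#' pipeline, with units, in one place. Stages run in dependency order:
#' synth (or user SWC input) -> polarity -> contacts -> build ->
#' simulate -> analyze.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "flybrainsim-out",
    stages = list(synth = FALSE, polarity = FALSE, contacts = FALSE,
                  build = FALSE, simulate = FALSE, analyze = FALSE),
    synth = list(n_neurons = 30L, connectivity = 0.01,
                 skeleton = list(axon_length_um = 300, dend_depth = 3L,
                                 seg_len_um = 15, box_um = 150)),
    polarity = list(granularity = 0.001),
    contacts = list(max_distance_um = 13, per_branch = FALSE),
    build = list(r_criterion = 0.01, b_exc = 2.2, ie_factor = 10,
                 tau_m_ms = 16, v_resting_mv = -70, v_threshold_mv = -45,
                 v_reset_mv = -55, t_refract_ms = 2,
                 c_per_area_pf_um2 = 0.008,
                 k = list(AMPA = 1 / 300, NMDA = 1 / 15000,
                          ACh = 1 / 3000, GABA_A = 1 / 300)),
    simulate = list(duration_ms = 2000, dt_ms = 0.1, tau_d_ms = 0,
                    p_v = 0.5, alpha_nmda = 0.6332, mg_mm = 1,
                    noise_mean_mv = -60, noise_sd_mv = 3,
                    rate_bin_ms = 100),
    analyze = list(hyperactivity_threshold_hz = 1.0, fano_trials = 10L,
                   rate_fit_bins = 20L))
}

#' Read / write a pipeline configuration (YAML)
#'
#' Round-trip is lossless; unknown keys are rejected at the top level.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `read_pipeline_config` returns the merged configuration;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  modifyList(base, user)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}

#' Run the model-construction and simulation pipeline
#'
#' Executes the enabled stages in dependency order, writing each
#' stage's artifacts under `config$out_dir` and recording a manifest
#' (file names, MD5 hashes, seed, package version). Re-running with an
#' identical configuration reproduces identical artifacts. A stage
#' failure halts the pipeline with the stage name in the error.
#'
#' @param config a configuration list (see
#'   [default_pipeline_config()]).
#' @return The manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible())
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  path <- function(f) file.path(config$out_dir, f)

  run_stage("synth", function() {
    sp <- config$synth
    state$skeletons <- synth_skeletons(
      sp$n_neurons, seed = config$seed,
      axon_length = sp$skeleton$axon_length_um,
      dend_depth = sp$skeleton$dend_depth,
      seg_len = sp$skeleton$seg_len_um, box = sp$skeleton$box_um)
    names(state$skeletons) <- sprintf("Cha-F-%06d",
                                      seq_along(state$skeletons))
    dir.create(path("swc"), showWarnings = FALSE)
    for (id in names(state$skeletons))
      write_swc(state$skeletons[[id]], path(file.path("swc",
                                                      paste0(id, ".swc"))))
    artifacts <<- c(artifacts, file.path("swc",
                                         paste0(names(state$skeletons),
                                                ".swc")))
    cn <- synth_connectome(sp$n_neurons, connectivity = sp$connectivity,
                           seed = config$seed)
    state$neurons <- cn$neurons
    state$contacts <- cn$contacts
    write.table(cn$neurons, path("neurons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_contacts_tsv(cn$contacts, path("contacts.tsv"))
    artifacts <<- c(artifacts, "neurons.tsv", "contacts.tsv")
  })

  run_stage("polarity", function() {
    cl <- if (!is.null(config$polarity$classifier_json))
      read_classifier_json(config$polarity$classifier_json)
    else default_polarity_classifier()
    state$polarity <- classify_polarity_batch(
      state$skeletons, classifier = cl,
      granularity = config$polarity$granularity)
    write_polarity_tsv(state$polarity, path("polarity.tsv"))
    artifacts <<- c(artifacts, "polarity.tsv")
  })

  run_stage("contacts", function() {
    labs <- lapply(state$polarity, `[[`, "node_labels")
    state$contacts <- contact_matrix(state$skeletons, labs,
                                     config$contacts$max_distance_um,
                                     config$contacts$per_branch)
    state$neurons <- data.frame(id = names(state$skeletons),
                                name = names(state$skeletons),
                                length = vapply(state$skeletons,
                                                total_skeleton_length,
                                                numeric(1)))
    write_contacts_tsv(state$contacts, path("contacts.tsv"))
    artifacts <<- c(artifacts, "contacts.tsv")
  })

  run_stage("build", function() {
    bc <- config$build
    state$model <- assemble_model(
      state$neurons, state$contacts,
      criteria = connection_criteria(config$contacts$max_distance_um,
                                     bc$r_criterion),
      scaling = synaptic_scaling(bc$b_exc, bc$ie_factor,
                                 unlist(bc$k)),
      tau_m = bc$tau_m_ms, V_resting = bc$v_resting_mv,
      V_threshold = bc$v_threshold_mv, V_reset = bc$v_reset_mv,
      T_refract = bc$t_refract_ms, c_per_area = bc$c_per_area_pf_um2)
    write_model_json(state$model, path("model.json"))
    artifacts <<- c(artifacts, "model.json")
  })

  run_stage("simulate", function() {
    sc <- config$simulate
    state$run <- run_simulation(
      state$model,
      simulation_config(duration = sc$duration_ms, dt = sc$dt_ms,
                        seed = config$seed, rate_bin = sc$rate_bin_ms),
      kinetics = receptor_kinetics(tau_d = sc$tau_d_ms, p_v = sc$p_v,
                                   alpha = sc$alpha_nmda, mg = sc$mg_mm),
      target_mean_V = sc$noise_mean_mv, target_sd_V = sc$noise_sd_mv)
    write.table(state$run$spikes, path("spikes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(state$run$rate, path("rate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, "spikes.tsv", "rate.tsv")
  })

  run_stage("analyze", function() {
    ac <- config$analyze
    dir.create(path("analysis"), showWarnings = FALSE)
    ei <- ei_index(state$model, weighted = TRUE)
    write.table(ei, path("analysis/ei_index.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    deg <- degree_stats(state$model)
    write.table(deg$per_neuron, path("analysis/degree.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hyper <- detect_hyperactivity(state$run$rate,
                                  ac$hyperactivity_threshold_hz)
    summary <- list(density = deg$density,
                    hyperactivity = list(prevalence = hyper$prevalence,
                                         onset_ms = hyper$onset))
    jsonlite::write_json(summary, path("analysis/summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    artifacts <<- c(artifacts, "analysis/ei_index.tsv",
                    "analysis/degree.tsv", "analysis/summary.json")
  })

  artifacts <- unique(artifacts)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("flybrainsim")),
    artifacts = lapply(setNames(artifacts, artifacts), function(f)
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f))))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
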