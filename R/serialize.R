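# YAML serialization of schemas and simulation specs, so runs can echo
# their configuration in a readable, diffable form.

#' Write / read a feature schema as YAML
#'
#' @param schema A [cohort_schema()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `mds_schema` (reader).
#' @export
write_schema_yaml <- function(schema, path) {
  yaml::write_yaml(list(gene_list = schema$gene_list,
                        pathway_groups = schema$pathway_groups,
                        karyotype_levels = schema$karyotype_levels,
                        min_feature_frequency = schema$min_feature_frequency),
                   path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cohort_schema(genes = x$gene_list,
                pathways = x$pathway_groups %||% list(),
                min_feature_frequency = x$min_feature_frequency %||% 0)
}

#' Write / read a simulation spec as YAML
#'
#' @param spec A [simulation_spec()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a `mds_sim_spec` (reader).
#' @export
write_sim_spec_yaml <- function(spec, path) {
  x <- unclass(spec)
  x$gene_probs <- apply(spec$gene_probs, 1L, as.numeric, simplify = FALSE)
  x$karyotype_probs <- apply(spec$karyotype_probs, 1L, as.numeric,
                             simplify = FALSE)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_spec_yaml
#' @export
read_sim_spec_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_spec(
    n_patients = x$n_patients, gene_names = x$gene_names,
    mixing_weights = unlist(x$mixing_weights),
    gene_probs = do.call(rbind, lapply(x$gene_probs, unlist)),
    karyotype_probs = do.call(rbind, lapply(x$karyotype_probs, unlist)),
    weibull_shape = unlist(x$weibull_shape),
    weibull_scale = unlist(x$weibull_scale),
    censor_rate = x$censor_rate,
    admin_censor_time = x$admin_censor_time %||% Inf,
    hma_prob = unlist(x$hma_prob), hsct_prob = unlist(x$hsct_prob),
    response_logodds = unlist(x$response_logodds), seed = x$seed)
}

#' Persist a fitted embedding as a versioned JSON bundle
#'
#' All encoder/decoder parameters, the loss trace and the configuration are
#' stored as plain JSON (matrices as nested arrays), so a fitted embedding
#' round-trips through text with full double precision.
#'
#' @param embedding A `mds_embedding`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `mds_embedding` (reader).
#' @export
write_embedding_json <- function(embedding, path) {
  x <- list(
    format = "mdsmc_embedding", version = 1L,
    feature_names = embedding$feature_names,
    patient_ids = embedding$patient_ids,
    config = unclass(embedding$config),
    loss_trace = embedding$loss_trace,
    coordinates = list(dim = dim(embedding$coordinates),
                       data = as.numeric(embedding$coordinates)),
    params = lapply(embedding$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_json
#' @export
read_embedding_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mdsmc_embedding")) {
    abort("not an mdsmc embedding bundle.")
  }
  params <- lapply(x$params, function(p) {
    dm <- unlist(p$dim)
    if (length(dm) == 2L) matrix(p$data, dm[1], dm[2]) else as.numeric(p$data)
  })
  cfg <- x$config
  config <- embedding_config(latent_dim = cfg$latent_dim,
                             epochs = cfg$epochs,
                             learning_rate = cfg$learning_rate,
                             loss = cfg$loss, seed = cfg$seed)
  coords <- matrix(x$coordinates$data, x$coordinates$dim[1],
                   x$coordinates$dim[2])
  rownames(coords) <- x$patient_ids
  colnames(coords) <- paste0("Z", seq_len(ncol(coords)))
  structure(list(coordinates = coords, patient_ids = x$patient_ids,
                 loss_trace = as.numeric(x$loss_trace),
                 params = params,
                 feature_names = as.character(x$feature_names),
                 config = config),
            class = "mds_embedding")
}
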