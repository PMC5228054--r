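# Model persistence (single-file JSON checkpoint, versioned schema) and
# structured YAML run configuration.

CHECKPOINT_SCHEMA <- 1L

#' Save a trained model as a single-file JSON checkpoint
#'
#' The checkpoint holds every learnable array, the Gaussian grid, the
#' energy scaler and the architecture hyperparameters, under a versioned
#' schema; it is plain text and fully reconstructs the model.
#'
#' @param params A [dtnn_init()] parameter set.
#' @param scaler An [energy_scaler()].
#' @param path Output path.
#' @param config Optional config snapshot to embed.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(params, scaler, path, config = NULL) {
  obj <- list(
    schema_version = CHECKPOINT_SCHEMA,
    architecture = list(
      B = params$B, n_factors = params$n_factors, H = params$H,
      n_passes = params$n_passes,
      cutoff = if (is.null(params$cutoff)) NA else params$cutoff,
      tied = params$tied, activation = params$activation,
      species = params$species
    ),
    grid = list(mu_min = params$grid$mu_min, mu_max = params$grid$mu_max,
                delta_mu = params$grid$delta_mu, sigma = params$grid$sigma,
                gamma = params$grid$gamma),
    scaler = list(E_mu = scaler$E_mu, E_sigma = scaler$E_sigma),
    weights = list(
      emb = params$emb,
      inter = lapply(params$inter, function(w) {
        list(W_cf = w$W_cf, b_f1 = w$b_f1, W_df = w$W_df, b_f2 = w$b_f2,
             W_fc = w$W_fc)
      }),
      head = list(W1 = params$head$W1, b1 = params$head$b1,
                  W2 = params$head$W2, b2 = params$head$b2)
    ),
    config = config
  )
  # 17 significant digits: decimal text that round-trips doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a JSON checkpoint
#'
#' @param path Checkpoint path.
#' @return List with `params` ([dtnn_init()]-shaped), `scaler` and the
#'   embedded `config` (or `NULL`).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != CHECKPOINT_SCHEMA) {
    stop("unsupported checkpoint schema: ", obj$schema_version, call. = FALSE)
  }
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  mat <- function(x) {
    # row-major nested arrays -> matrix
    do.call(rbind, lapply(x, num))
  }
  a <- obj$architecture
  grid <- gaussian_grid(obj$grid$mu_min, obj$grid$mu_max, obj$grid$delta_mu,
                        obj$grid$sigma, gamma = obj$grid$gamma)
  cutoff <- if (is.null(a$cutoff) || is.na(a$cutoff)) NULL else a$cutoff
  species <- sort(as.integer(num(a$species)))
  params <- dtnn_init(species, grid, B = a$B, n_factors = a$n_factors,
                      H = a$H, n_passes = a$n_passes, cutoff = cutoff,
                      tied = isTRUE(a$tied), activation = a$activation,
                      seed = 0L)
  emb <- mat(obj$weights$emb)
  colnames(emb) <- as.character(species)
  params$emb <- emb
  params$inter <- lapply(obj$weights$inter, function(w) {
    list(W_cf = mat(w$W_cf), b_f1 = num(w$b_f1),
         W_df = mat(w$W_df), b_f2 = num(w$b_f2),
         W_fc = mat(w$W_fc))
  })
  params$head <- list(W1 = mat(obj$weights$head$W1),
                      b1 = num(obj$weights$head$b1),
                      W2 = num(obj$weights$head$W2),
                      b2 = num(obj$weights$head$b2))
  list(params = params,
       scaler = energy_scaler(obj$scaler$E_mu, obj$scaler$E_sigma),
       config = obj$config)
}

#' Read a structured YAML run configuration
#'
#' Nested sections `data`, `grid`, `model`, `train`, `synth`, `probe`;
#' missing sections fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of config sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}

config_grid <- function(cfg) {
  g <- cfg$grid
  gaussian_grid(
    mu_min = g$mu_min %||% -1, mu_max = g$mu_max %||% 10,
    delta_mu = g$delta_mu %||% 0.2, sigma = g$sigma %||% 0.2,
    gamma = g$gamma
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
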