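config_keys <- c("p", "period", "N", "leak", "c", "sigma", "h", "s1",
                 "centered", "kernel", "delay", "I_ext", "schema")

#' Load a model configuration file
#'
#' Reads a JSON model description and builds the corresponding `nf_model`.
#' Recognized keys: `p` (populations, must be 1), `period`, `N` (grid
#' size), `leak`, `c` (delay scale), `sigma` (gain), `h` (threshold), `s1`
#' (sigmoid slope), `centered`, `kernel` (`{type: "cosine", coeffs:
#' [[k, a], ...]}` or `{type: "matrix", values}`), `delay` (`{type:
#' "ring"}` or `{type: "matrix", values}`), `I_ext` (constant or vector),
#' and `schema`. Unknown keys are rejected; omitted keys get the reference
#' defaults.
#'
#' @param path JSON file.
#' @return an `nf_model` with the raw configuration attached as attribute
#'   `"config"`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg) || is.null(names(cfg)) || !length(cfg))
    stop("config must be a JSON object")
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  model <- model_from_config(cfg)
  attr(model, "config") <- cfg
  model
}

model_from_config <- function(cfg) {
  get_or <- function(key, default) if (is.null(cfg[[key]])) default
    else cfg[[key]]
  p <- get_or("p", 1L)
  if (p != 1L) stop("only one-population models are supported (p = 1)")
  period <- get_or("period", 2 * pi)
  n <- get_or("N", 128L)
  leak <- get_or("leak", 1)
  sigma <- get_or("sigma", 1)
  h <- get_or("h", 0)
  s1 <- get_or("s1", 0.25)
  centered <- get_or("centered", TRUE)
  if (leak <= 0 || sigma <= 0 || s1 <= 0)
    stop("physical parameters 'leak', 'sigma', 's1' must be positive")
  kernel <- get_or("kernel", list(type = "cosine", coeffs = list()))
  if (identical(kernel$type, "cosine")) {
    co <- kernel$coeffs
    if (is.list(co)) co <- do.call(rbind, co)
    if (is.null(co) || !length(co)) co <- matrix(numeric(0), 0L, 2L)
    kernel$coeffs <- matrix(as.numeric(co), ncol = 2L)
  }
  delay <- get_or("delay", list(type = "ring"))
  if (identical(delay$type, "ring")) {
    cc <- get_or("c", 1)
    if (cc < 0) stop("validation error: delay scale 'c' must be >= 0")
    delay <- list(type = "ring", c = cc)
  }
  neural_field_model(
    ring_grid(n, period), leak = leak, kernel = kernel, delay = delay,
    sigmoid = sigmoid_spec(gain = sigma, threshold = h, slope = s1,
                           centered = centered),
    I_ext = get_or("I_ext", 0)
  )
}

#' Save a model configuration
#'
#' Writes the JSON configuration of a model such that
#' `load_model_config(save_model_config(m, path))` reproduces it.
#'
#' @param model an `nf_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
save_model_config <- function(model, path) {
  stopifnot(inherits(model, "nf_model"))
  kernel <- if (model$kernel$type == "cosine") {
    co <- model$kernel$coeffs
    list(type = "cosine",
         coeffs = lapply(seq_len(nrow(co)),
                         function(i) unname(c(co[i, 1L], co[i, 2L]))))
  } else list(type = "matrix", values = model$kernel$values)
  delay <- if (model$delay$type == "ring") list(type = "ring")
    else list(type = "matrix", values = model$delay$values)
  cfg <- list(
    p = 1L, period = model$grid$period, N = length(model$grid$nodes),
    leak = model$leak, sigma = model$sigmoid$gain,
    h = model$sigmoid$threshold, s1 = model$sigmoid$slope,
    centered = model$sigmoid$centered, kernel = kernel, delay = delay,
    I_ext = if (is.function(model$I_ext))
      stop("cannot serialize a functional external current")
    else model$I_ext,
    schema = "delayfield-model-1")
  if (model$delay$type == "ring") cfg$c <- model$delay$c
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the reference model fixtures
#'
#' Emits the printed reference configurations as JSON files:
#' `ring.json` (unit leak, kernel `J(z) = -1 + 1.5 cos(2z)`, ring delay
#' with `c = 1` -- the model whose generator eigenvalues accumulate at
#' `-1`), `ring_sweep.json` (the same kernel with `c` and `sigma` as sweep
#' placeholders for bifurcation diagrams), and `toy0.json`
#' (zero-connectivity sanity model that decouples into independent leaks).
#'
#' @param outdir writable output directory (created if missing).
#' @return character vector of paths written.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- rbind(c(0, -1), c(2, 1.5))
  paths <- c(
    ring = file.path(outdir, "ring.json"),
    ring_sweep = file.path(outdir, "ring_sweep.json"),
    toy0 = file.path(outdir, "toy0.json"))
  save_model_config(make_ring_model(ref, c = 1, gain = 1, n = 64),
                    paths[["ring"]])
  save_model_config(make_ring_model(ref, c = 1, gain = 1, n = 64),
                    paths[["ring_sweep"]])
  save_model_config(make_ring_model(matrix(numeric(0), 0L, 2L), c = 0.5,
                                    gain = 1, n = 32), paths[["toy0"]])
  paths
}
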