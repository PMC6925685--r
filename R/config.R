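#' Read a run configuration file
#'
#' YAML file exposing the standard configuration surface:
#' \tabular{ll}{
#'   `w1`, `w2` \tab inertia weight at the start / end of the run \cr
#'   `c1i`, `c1f` \tab cognitive coefficient at start / end \cr
#'   `c2i`, `c2f` \tab social coefficient at start / end \cr
#'   `particle_num` \tab number of particles \cr
#'   `MAXOBJ` \tab objective-call budget \cr
#'   `MAXITER` \tab iteration budget; when set, `MAXOBJ` is ignored \cr
#'   `programs` \tab list of predictor names forming the committee \cr
#'   `weights` \tab optional named map of fixed per-program weights;
#'     those dimensions are frozen during optimization \cr
#'   `seed` \tab RNG seed \cr
#'   `weights_per` \tab `"class"` or `"predictor"` \cr
#' }
#' Unset keys fall back to the [swarm_config()] defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with `config` (a [swarm_config()]), `programs`
#'   (character or `NULL`), `fixed` (named numeric or `NULL`), and
#'   `weights_per`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  config <- swarm_config(
    omega_max = pick("w1", 0.9), omega_min = pick("w2", 0.4),
    c1_max = pick("c1i", 2.5), c1_min = pick("c1f", 0.5),
    c2_min = pick("c2i", 0.5), c2_max = pick("c2f", 2.5),
    n_particles = pick("particle_num", 25L),
    max_calls = pick("MAXOBJ", 1000L),
    max_iter = raw[["MAXITER"]],
    seed = pick("seed", 1L))
  fixed <- raw[["weights"]]
  if (!is.null(fixed)) {
    fixed <- unlist(fixed)
    if (is.null(names(fixed)) || any(names(fixed) == "")) {
      stop("config 'weights' must be a named map of program -> weight",
           call. = FALSE)
    }
  }
  list(config = config,
       programs = if (!is.null(raw[["programs"]]))
         as.character(unlist(raw[["programs"]])),
       fixed = fixed,
       weights_per = pick("weights_per", "class"))
}

#' Persist fitted fusion weights as JSON
#'
#' Weights are stored with explicit predictor names, locations and
#' mode so committee mismatches are detectable at prediction time.
#'
#' @param weights A [weight_vector()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  jsonlite::write_json(
    list(mode = weights$mode,
         committee_kind = weights$vocabulary$kind,
         predictors = weights$predictors,
         locations = weights$vocabulary$locations,
         values = unname(weights$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- location_vocabulary(obj$committee_kind)
  if (!identical(vocab$locations, as.character(obj$locations))) {
    stop("weights file location list does not match the ", obj$committee_kind,
         " vocabulary", call. = FALSE)
  }
  weight_vector(as.numeric(obj$values), obj$mode,
                as.character(obj$predictors), vocab)
}
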