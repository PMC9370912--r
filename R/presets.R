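# Registry, validation and serialization of rhythm presets. Each preset is a
# JSON file under inst/extdata/presets/ holding {model, rhythm, params,
# time_scale, gain, notes} and, for arrhythmias that modify a normal row, a
# "base" key plus only the changed parameter fields (sparse overrides).

preset_dir <- function() {
  system.file("extdata", "presets", package = "ecgsim", mustWork = TRUE)
}

.preset_cache <- new.env(parent = emptyenv())

read_preset_file <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$params <- rapply(raw$params, identity, how = "replace")
  raw
}

preset_registry <- function() {
  if (is.null(.preset_cache$registry)) {
    files <- list.files(preset_dir(), pattern = "\\.json$", full.names = TRUE)
    reg <- lapply(files, read_preset_file)
    names(reg) <- vapply(reg, function(p) paste(p$model, p$rhythm, sep = "/"),
                         character(1))
    if (anyDuplicated(names(reg))) abort("duplicate preset keys in registry")
    .preset_cache$registry <- reg
  }
  .preset_cache$registry
}

# deep-merge sparse overrides onto a base raw parameter list; atomic leaves
# (including vectors like K) are replaced wholesale
merge_params <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  utils::modifyList(base, overrides)
}

resolve_raw_preset <- function(raw, registry = preset_registry()) {
  if (!is.null(raw$base)) {
    key <- paste(raw$model, raw$base, sep = "/")
    base <- registry[[key]]
    if (is.null(base)) {
      abort(paste0("base preset '", raw$base, "' not found for model ",
                   raw$model))
    }
    raw$params <- merge_params(base$params, raw$params)
  }
  raw
}

# dotted-path overrides, e.g. list("pacemakers.AV.K" = 0, "H" = 2.8)
apply_overrides <- function(params, overrides) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- params
    # verify the path exists before assigning
    for (p in path) {
      if (!is.list(node) || is.null(node[[p]])) {
        abort(paste0("unknown parameter override '", nm, "'"))
      }
      node <- node[[p]]
    }
    params[[path]] <- overrides[[nm]]
  }
  params
}

build_params <- function(model, raw, time_scale) {
  switch(model,
    heterogeneous = het_params(
      pacemakers = lapply(raw$pacemakers, function(p) do.call(pacemaker_params, p)),
      muscles = lapply(raw$muscles, function(m) do.call(muscle_params, m)),
      z0 = raw$z0,
      lead_weights = if (!is.null(raw$lead_weights)) {
        as_tibble(raw$lead_weights)
      } else {
        default_lead_weights(raw$z0)
      }
    ),
    reaction_diffusion = rd_params(
      H = raw$H, C = raw$C, beta = raw$beta, K = raw$K, Gamma_t = time_scale
    ),
    ring = ring_params(
      nodes = raw$nodes, k = raw$k, tau = raw$tau, alpha = raw$alpha,
      beta_G = raw$beta_G, beta_T = time_scale
    ),
    quasi_periodic = qp_params(
      kernels = lapply(raw$kernels, function(k) {
        gaussian_kernel(k$a, k$b, k$theta)
      }),
      hr = raw$hr, A = raw$A, fr = raw$fr,
      tachogram = if (!is.null(raw$tachogram)) {
        do.call(rr_tachogram_spec, raw$tachogram)
      }
    )
  )
}

#' Retrieve a rhythm preset
#'
#' Looks up a shipped preset by `(model, rhythm)`, resolves any sparse
#' overrides onto its normal-rhythm base row, applies user parameter
#' overrides, validates, and returns an independent copy. The shipped registry
#' covers the tabulated normal rhythms, the two conduction blocks of the
#' heterogeneous model, four reaction-diffusion and three ring arrhythmias,
#' and five quasi-periodic arrhythmias.
#'
#' @param model Model identifier.
#' @param rhythm Rhythm name, e.g. `"normal"`, `"sinus_tachycardia"`.
#' @param overrides Optional named list of parameter overrides with
#'   dotted-path names (e.g. `list("pacemakers.AV.K" = 0, "H" = 2.9)`),
#'   mirroring a parameter-settings menu.
#' @param gain Optional replacement for the preset's target R-peak amplitude
#'   (mV); must lie in the 0.5-4 mV output range.
#' @return A `rhythm_preset` with elements `model`, `rhythm`, `params` (built
#'   parameter object), `raw_params`, `time_scale`, `gain`, `notes`.
#' @export
get_preset <- function(model, rhythm, overrides = NULL, gain = NULL) {
  model <- check_model(model)
  registry <- preset_registry()
  key <- paste(model, rhythm, sep = "/")
  if (is.null(registry[[key]])) {
    valid <- sub("^.*/", "", grep(paste0("^", model, "/"), names(registry),
                                  value = TRUE))
    abort(paste0(
      "no preset '", rhythm, "' for model '", model, "'; available: ",
      paste(sort(valid), collapse = ", ")
    ))
  }
  raw <- resolve_raw_preset(registry[[key]], registry)
  if (!is.null(overrides)) raw$params <- apply_overrides(raw$params, overrides)
  if (!is.null(gain)) raw$gain <- gain
  if (raw$gain < 0.5 || raw$gain > 4) {
    abort("`gain` must lie in the 0.5-4 mV output range")
  }
  out <- list(
    model = model, rhythm = raw$rhythm,
    params = build_params(model, raw$params, raw$time_scale),
    raw_params = raw$params,
    time_scale = raw$time_scale, gain = raw$gain, notes = raw$notes
  )
  class(out) <- "rhythm_preset"
  out
}

#' @export
print.rhythm_preset <- function(x, ...) {
  cat("<rhythm_preset>", paste0(x$model, "/", x$rhythm),
      "| time_scale:", format(x$time_scale),
      "| gain:", format(x$gain), "mV\n")
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' List the shipped rhythm presets
#'
#' @return A tibble with columns `model`, `rhythm`, `notes`, in deterministic
#'   order (model order as in the package, then rhythm alphabetically).
#' @export
list_presets <- function() {
  reg <- preset_registry()
  out <- tibble(
    model = unname(vapply(reg, `[[`, character(1), "model")),
    rhythm = unname(vapply(reg, `[[`, character(1), "rhythm")),
    notes = unname(vapply(reg, `[[`, character(1), "notes"))
  )
  out %>%
    mutate(.m = match(.data$model, names(MODELS))) %>%
    arrange(.data$.m, .data$rhythm) %>%
    select(-".m")
}

#' Validate a serialized preset
#'
#' Checks a raw preset (a list, or a path to a preset JSON file) for schema
#' completeness against its model's parameter layout, numeric finiteness,
#' kernel-width positivity, delay non-negativity, and the 0.5-4 mV gain range.
#' On success the built `rhythm_preset` is returned; on failure a
#' `preset_validation_report` listing every violation.
#'
#' @param raw A list with fields `model`, `rhythm`, `params`, `time_scale`,
#'   `gain` (optionally `base`, `notes`), or a path to such a JSON file.
#' @return A `rhythm_preset`, or a `preset_validation_report` with elements
#'   `valid = FALSE` and `problems` (character).
#' @export
validate_preset <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) abort(paste0("no such preset file: ", raw))
    raw <- read_preset_file(raw)
  }
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  raw2 <- NULL

  for (f in c("model", "rhythm", "params", "time_scale", "gain")) {
    if (is.null(raw[[f]])) add(paste0("missing field: ", f))
  }
  if (!is.null(raw$model) && !raw$model %in% names(MODELS)) {
    add(paste0("unknown model '", raw$model, "'"))
  }
  if (length(problems) == 0) {
    raw2 <- tryCatch(
      resolve_raw_preset(raw),
      error = function(e) {
        add(conditionMessage(e))
        NULL
      }
    )
    if (!is.null(raw2)) {
      p <- raw2$params
      if (raw2$model == "heterogeneous" && is.null(p$lead_weights)) {
        p$lead_weights <- default_lead_weights(if (is.null(p$z0)) 0 else p$z0)
      }
      if (raw2$model == "reaction_diffusion") p$Gamma_t <- raw2$time_scale
      if (raw2$model == "ring") p$beta_T <- raw2$time_scale
      if (raw2$model == "quasi_periodic") {
        if (is.null(p$A)) add("missing field(s) in params: A")
        if (is.null(p$fr)) add("missing field(s) in params: fr")
      }
      add(validate_params(raw2$model, p))
      if (is.numeric(raw2$time_scale) && raw2$time_scale <= 0) {
        add("time_scale must be > 0")
      }
      if (is.numeric(raw2$gain) && (raw2$gain < 0.5 || raw2$gain > 4)) {
        add("gain must lie in the 0.5-4 mV output range")
      }
    }
  }
  if (length(problems)) {
    return(structure(list(valid = FALSE, problems = problems),
                     class = "preset_validation_report"))
  }
  out <- list(
    model = raw2$model, rhythm = raw2$rhythm,
    params = build_params(raw2$model, raw2$params, raw2$time_scale),
    raw_params = raw2$params,
    time_scale = raw2$time_scale, gain = raw2$gain,
    notes = raw2$notes %||% ""
  )
  class(out) <- "rhythm_preset"
  out
}

#' @export
print.preset_validation_report <- function(x, ...) {
  cat("<preset_validation_report> INVALID\n")
  for (p in x$problems) cat(" -", p, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fields in which an arrhythmia preset differs from its normal base
#'
#' Compares the resolved parameter set of a shipped override preset with its
#' model's normal row and returns the dotted paths of every differing leaf.
#' Used to verify that arrhythmia rows change only the fields they list.
#'
#' @param model Model identifier.
#' @param rhythm Rhythm name of an override preset.
#' @return Character vector of dotted leaf paths (e.g. `"pacemakers.AV.K"`).
#' @export
preset_diff <- function(model, rhythm) {
  arr <- get_preset(model, rhythm)
  base <- get_preset(model, "normal")
  flat_a <- unlist(arr$raw_params)
  flat_b <- unlist(base$raw_params)
  keys <- union(names(flat_a), names(flat_b))
  changed <- keys[vapply(keys, function(k) {
    !identical(flat_a[[k]], flat_b[[k]])
  }, logical(1))]
  extra <- character(0)
  if (!identical(arr$time_scale, base$time_scale)) extra <- c(extra, "time_scale")
  sort(c(changed, extra))
}
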