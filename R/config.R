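#' Load a model configuration file
#'
#' Reads a YAML (or JSON) configuration with sections `populations`,
#' `interactions`, `chi`, `proportions`, `conductance_model`, and optional
#' `init` (initial-condition laws) and `run` (default run options). The
#' document is validated against the model's constraints; every violation is
#' reported with the offending key path. Defaults are filled in and can be
#' echoed back with [write_config()], so any run is reproducible from its
#' emitted effective configuration plus the seed.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list with elements `model` (an [model_spec()]), `laws` (an
#'   [init_law_spec()]) and `run` (a list of run options, possibly empty).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  errs <- character(0)
  fail <- function(key, msg) errs <<- c(errs, sprintf("%s: %s", key, msg))

  if (is.null(doc$populations) || !length(doc$populations)) {
    fail("populations", "at least one population is required")
  }
  cm <- doc$conductance_model %||% "sign_preserving"
  if (!cm %in% c("sign_preserving", "simple")) {
    fail("conductance_model", "must be 'sign_preserving' or 'simple'")
  }

  pops <- list()
  for (lab in names(doc$populations)) {
    pd <- doc$populations[[lab]]
    key <- paste0("populations.", lab)
    kind <- pd$model_kind %||% "fhn"
    if (!kind %in% c("fhn", "hh")) {
      fail(paste0(key, ".model_kind"), "must be 'fhn' or 'hh'")
      next
    }
    for (f in c("a_r", "a_d")) {
      if (!is.null(pd[[f]]) && pd[[f]] <= 0) {
        fail(paste0(key, ".", f), "must be > 0")
      }
    }
    if (!is.null(pd$sigma_V) && pd$sigma_V < 0) {
      fail(paste0(key, ".sigma_V"), "must be >= 0")
    }
    sg <- pd$sigmoid
    if (!is.null(sg) && (!is.null(sg$C) && sg$C <= 0 ||
                         !is.null(sg$lambda) && sg$lambda <= 0)) {
      fail(paste0(key, ".sigmoid"), "C and lambda must be > 0")
    }
    pops[[lab]] <- tryCatch({
      args <- list(label = lab, model_kind = kind)
      for (f in c("sigma_V", "a_r", "a_d", "sigmoid", "fhn", "hh")) {
        if (!is.null(pd[[f]])) args[[f]] <- pd[[f]]
      }
      do.call(population_spec, args)
    }, error = function(e) {
      fail(key, conditionMessage(e)); NULL
    })
  }
  pops <- pops[!vapply(pops, is.null, TRUE)]
  labels <- names(pops)

  inter <- NULL
  if (!is.null(doc$interactions)) {
    rows <- lapply(seq_along(doc$interactions), function(i) {
      r <- doc$interactions[[i]]
      key <- sprintf("interactions[%d]", i)
      for (f in c("from", "to")) {
        if (is.null(r[[f]])) fail(key, sprintf("missing '%s'", f))
        else if (!r[[f]] %in% labels) {
          fail(paste0(key, ".", f),
               sprintf("unknown population '%s'", r[[f]]))
        }
      }
      if (cm == "simple" && !is.null(r$theta)) {
        fail(paste0(key, ".theta"),
             "theta is unused by the simple conductance model; remove it")
      }
      tibble(from = r$from %||% NA_character_, to = r$to %||% NA_character_,
             V_rev = r$V_rev %||% 0, J_bar = r$J_bar %||% 0,
             sigma_J = r$sigma_J %||% 0, theta = r$theta %||% NA_real_)
    })
    inter <- bind_rows(rows)
  }

  chi <- tryCatch({
    cd <- doc$chi %||% list()
    chi_fun(shape = cd$shape %||% "trapezoid", lo = cd$lo %||% 0.05,
            hi = cd$hi %||% 0.95, peak = cd$peak %||% 1,
            ramp = cd$ramp %||% 0.05)
  }, error = function(e) { fail("chi", conditionMessage(e)); NULL })

  props <- if (!is.null(doc$proportions)) unlist(doc$proportions) else NULL
  if (!is.null(props)) {
    if (is.null(names(props)) || !setequal(names(props), labels)) {
      fail("proportions", "must be named by the population labels")
    } else if (any(props <= 0) || abs(sum(props) - 1) > 1e-9) {
      fail("proportions", "must be positive and sum to 1")
    }
  }

  if (length(errs)) {
    abort(paste0("invalid configuration:\n", paste0("  - ", errs, collapse = "\n")),
          class = "mfneuron_config_error")
  }

  model <- model_spec(pops, inter, chi = chi, proportions = props,
                      conductance_model = cm)

  overrides <- list()
  if (!is.null(doc$init)) {
    for (lab in names(doc$init)) {
      if (!lab %in% labels) {
        abort(sprintf("init.%s: unknown population", lab),
              class = "mfneuron_config_error")
      }
      ov <- list()
      for (f in names(doc$init[[lab]])) {
        ld <- doc$init[[lab]][[f]]
        if (f == "J0" && !is.null(names(ld)) && is.null(ld$dist)) {
          ov$J0 <- lapply(ld, .law_from_list)
        } else {
          ov[[f]] <- .law_from_list(ld)
        }
      }
      overrides[[lab]] <- ov
    }
  }
  laws <- init_law_spec(model, overrides)
  list(model = model, laws = laws, run = doc$run %||% list())
}

.law_from_list <- function(ld) {
  if (inherits(ld, "nm_law")) return(ld)
  if (is.null(ld$dist)) abort("law descriptor needs a 'dist' field")
  switch(ld$dist,
    normal = law_normal(ld$mean, ld$sd),
    uniform = law_uniform(ld$min, ld$max),
    beta_scaled = law_beta(ld$shape1 %||% 2, ld$shape2 %||% 2,
                           ld$lo %||% 0.1, ld$hi %||% 0.9),
    gamma = law_gamma(ld$mean, ld$shape %||% 4),
    constant = law_const(ld$value),
    abort(sprintf("unsupported law family '%s'", ld$dist))
  )
}

.law_to_list <- function(l) {
  out <- unclass(l)
  out
}

#' Write the effective configuration of a model
#'
#' Emits the fully resolved configuration (all defaults filled in) as YAML,
#' such that [load_config()] on the emitted file reproduces the identical
#' model, laws and run options.
#'
#' @param model an [model_spec()].
#' @param laws an [init_law_spec()] (optional; defaults are emitted).
#' @param run list of run options to echo.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, laws = NULL, run = list(), path) {
  stopifnot(inherits(model, "nm_model"))
  if (is.null(laws)) laws <- init_law_spec(model)
  pops <- lapply(model$populations, function(p) {
    out <- list(model_kind = p$model_kind, sigma_V = p$sigma_V,
                a_r = p$a_r, a_d = p$a_d, sigmoid = p$sigmoid)
    if (p$model_kind == "fhn") out$fhn <- p$fhn else out$hh <- p$hh
    out
  })
  inter <- lapply(seq_len(nrow(model$interactions)), function(i) {
    r <- as.list(model$interactions[i, ])
    if (model$conductance_model == "simple") r$theta <- NULL
    r
  })
  init <- lapply(laws$laws, function(l) {
    out <- lapply(l[setdiff(names(l), "J0")], .law_to_list)
    if (!is.null(l$J0)) out$J0 <- lapply(l$J0, .law_to_list)
    out
  })
  doc <- list(
    populations = pops,
    interactions = inter,
    chi = unclass(model$chi)[c("shape", "lo", "hi", "peak", "ramp")],
    proportions = as.list(model$proportions),
    conductance_model = model$conductance_model,
    init = init
  )
  if (length(run)) doc$run <- run
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
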