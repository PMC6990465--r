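#' Read a native model specification
#'
#' The native declarative format is a single YAML (or JSON) document with
#' blocks `states`, `parameters`, `reactions`, optional `couplings`, and
#' `experiments`.  Rate and observable expressions are parsed with a
#' restricted arithmetic grammar (names, numbers, `+ - * / ^`,
#' parentheses) -- a model file can never execute code.  Unknown keys are
#' rejected with an error naming the key.
#'
#' @param path path to the model spec file.
#' @return a list with `model` ([parametric_model()]), `space`
#'   ([parameter_space()]), `catalog` ([projection_catalog()]) and
#'   `experiments` (list of [experiment()]).
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("model spec '%s' does not exist", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  tf_check_keys(doc, c("name", "states", "parameters", "reactions",
                       "couplings", "experiments"), "model spec")
  for (blk in c("states", "parameters", "reactions", "experiments")) {
    if (is.null(doc[[blk]])) stop(sprintf("model spec: missing block '%s'", blk), call. = FALSE)
  }

  st <- lapply(doc$states, function(s) {
    tf_check_keys(s, c("name", "init"), "state")
    s
  })
  state_names <- vapply(st, function(s) s$name, "")
  x0 <- stats::setNames(vapply(st, function(s) as.numeric(s$init %||% 0), 0), state_names)

  pars <- lapply(doc$parameters, function(p) {
    tf_check_keys(p, c("name", "lower", "upper", "scale", "reducible", "projection"),
                  "parameter")
    p
  })
  pnames <- vapply(pars, function(p) p$name, "")
  lower <- stats::setNames(vapply(pars, function(p) as.numeric(p$lower), 0), pnames)
  upper <- stats::setNames(vapply(pars, function(p) as.numeric(p$upper), 0), pnames)
  scale <- vapply(pars, function(p) p$scale %||% "linear", "")
  reducible <- pnames[vapply(pars, function(p) isTRUE(p$reducible), TRUE)]
  proj <- stats::setNames(vapply(pars, function(p) as.numeric(p$projection %||% 0), 0),
                          pnames)[reducible]

  reactions <- lapply(doc$reactions, function(r) {
    tf_check_keys(r, c("stoichiometry", "rate", "constant"), "reaction")
    list(stoichiometry = unlist(r$stoichiometry), rate = r$rate, constant = r$constant)
  })

  model <- parametric_model(state_names, x0, pnames, reactions)
  space <- parameter_space(lower, upper, scale, parameter_names = pnames)
  catalog <- projection_catalog(pnames, reducible, proj,
                                couplings = lapply(doc$couplings %||% list(), unlist))

  experiments <- lapply(doc$experiments, function(e) {
    tf_check_keys(e, c("name", "times", "observables", "parameter_overrides",
                       "state_overrides", "events"), "experiment")
    for (o in e$observables) tf_check_keys(o, c("name", "expr"), "observable")
    obs <- stats::setNames(vapply(e$observables, function(o) o$expr, ""),
                           vapply(e$observables, function(o) o$name, ""))
    ev <- if (!is.null(e$events)) do.call(rbind, lapply(e$events, function(v) {
      tf_check_keys(v, c("time", "state", "amount"), "event")
      data.frame(time = as.numeric(v$time), state = v$state,
                 amount = as.numeric(v$amount))
    }))
    experiment(e$name, as.numeric(e$times), obs,
               parameter_overrides = if (!is.null(e$parameter_overrides))
                 unlist(e$parameter_overrides),
               state_overrides = if (!is.null(e$state_overrides))
                 unlist(e$state_overrides),
               events = ev)
  })

  list(model = model, space = space, catalog = catalog, experiments = experiments)
}

tf_check_keys <- function(x, allowed, where) {
  if (!is.list(x)) stop(sprintf("malformed %s entry", where), call. = FALSE)
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown key '%s' in %s", unknown[1L], where), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a native model specification
#'
#' Inverse of [read_model_spec()]: `read_model_spec(write_model_spec(...))`
#' reproduces an equal problem.
#'
#' @param model,space,catalog,experiments the problem components.
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, space, catalog, experiments, path) {
  doc <- list(
    states = lapply(model$state_names, function(s)
      list(name = s, init = unname(model$x0[[s]]))),
    parameters = lapply(model$parameter_names, function(p) {
      entry <- list(name = p, lower = unname(space$lower[[p]]),
                    upper = unname(space$upper[[p]]),
                    scale = unname(space$scale[[p]]),
                    reducible = p %in% catalog$reducible)
      if (entry$reducible) entry$projection <- unname(catalog$projection_values[[p]])
      entry
    }),
    reactions = lapply(seq_along(model$rate_strings), function(j) {
      col <- model$stoichiometry[, j]
      list(stoichiometry = as.list(col[col != 0]),
           rate = model$rate_strings[[j]],
           constant = model$multiplicative_constants[[j]])
    }),
    experiments = lapply(experiments, function(e) {
      entry <- list(name = e$name, times = as.list(e$times),
                    observables = lapply(names(e$observables), function(o)
                      list(name = o, expr = unname(e$observables[[o]]))))
      if (!is.null(e$parameter_overrides))
        entry$parameter_overrides <- as.list(e$parameter_overrides)
      if (!is.null(e$state_overrides))
        entry$state_overrides <- as.list(e$state_overrides)
      if (!is.null(e$events))
        entry$events <- lapply(seq_len(nrow(e$events)), function(i)
          list(time = e$events$time[i], state = e$events$state[i],
               amount = e$events$amount[i]))
      entry
    }))
  if (length(catalog$couplings) > 0L) {
    doc$couplings <- lapply(catalog$couplings, as.list)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a measurement data table
#'
#' Delimited text (CSV or TSV; the delimiter is sniffed from the header)
#' with columns `experiment, observable, time, value, sigma`.  Rows may
#' come in any order: the table is canonicalized on load to the prediction
#' order (experiment list order, then declared observable order, then time
#' ascending) and checked to cover each experiment's full observable-time
#' grid exactly once.  Strictly positive `sigma` is enforced.
#'
#' @param path path to the data file.
#' @param experiments the experiment list the table must match.
#' @return a [tf_dataset()] in canonical order.
#' @export
read_data_table <- function(path, experiments) {
  if (!file.exists(path)) stop(sprintf("data table '%s' does not exist", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("experiment", "observable", "time", "value", "sigma")
  if (!all(need %in% names(df))) {
    stop(sprintf("data table must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(df$sigma)) || any(df$sigma <= 0)) {
    stop("data table: sigma must be strictly positive", call. = FALSE)
  }
  y0 <- numeric(0); sigma <- numeric(0)
  for (ex in experiments) {
    for (obs in names(ex$observables)) {
      for (t in ex$times) {
        hit <- which(df$experiment == ex$name & df$observable == obs &
                       abs(df$time - t) < 1e-9)
        if (length(hit) != 1L) {
          stop(sprintf("data table: need exactly one row for experiment '%s', observable '%s', time %g (found %d)",
                       ex$name, obs, t, length(hit)), call. = FALSE)
        }
        y0 <- c(y0, df$value[hit])
        sigma <- c(sigma, df$sigma[hit])
      }
    }
  }
  n_expected <- sum(vapply(experiments, function(e)
    length(e$observables) * length(e$times), 0))
  if (nrow(df) != n_expected) {
    stop(sprintf("data table has %d rows but the experiments define %d measurements",
                 nrow(df), n_expected), call. = FALSE)
  }
  tf_dataset(y0, sigma)
}

#' Write a measurement data table
#'
#' @param dataset a [tf_dataset()] in canonical order.
#' @param experiments the experiment list defining that order.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_data_table <- function(dataset, experiments, path) {
  rows <- list()
  i <- 1L
  for (ex in experiments) {
    for (obs in names(ex$observables)) {
      for (t in ex$times) {
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = ex$name, observable = obs, time = t,
          value = dataset$y0[i], sigma = dataset$sigma[i])
        i <- i + 1L
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with optional blocks `filter` ([filter_config()] fields), `sampler`
#' ([sampler_config()] fields), a mandatory `initial_point` (named
#' parameter values), and optional `score` (`type`, `q`).  Unknown keys
#' are rejected with an error naming the key.
#'
#' @param path path to the config file.
#' @return a list with `filter_config`, `initial_point`, `score`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("run config '%s' does not exist", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  tf_check_keys(doc, c("filter", "sampler", "initial_point", "score"), "run config")
  if (is.null(doc$initial_point)) {
    stop("run config: 'initial_point' is mandatory", call. = FALSE)
  }
  sflds <- doc$sampler %||% list()
  tf_check_keys(sflds, names(formals(sampler_config)), "sampler config")
  sampler <- do.call(sampler_config, sflds)
  fflds <- doc$filter %||% list()
  tf_check_keys(fflds, setdiff(names(formals(filter_config)), "sampler"), "filter config")
  fflds$sampler <- sampler
  list(filter_config = do.call(filter_config, fflds),
       initial_point = unlist(doc$initial_point),
       score = doc$score %||% list(type = "nll", q = 0.95))
}

#' Read and validate a complete filtering problem
#'
#' Loads model spec, data table and run configuration, cross-validates
#' them (observables against states, reducible names against parameters,
#' strictly positive sigma), and checks that the configured initial point
#' is viable -- a non-viable initial point is reported with its score and
#' the threshold before any search is attempted.
#'
#' @param model_path,data_path,config_path the three input files.
#' @return a list with `problem` ([tf_problem()]), `init_point`,
#'   `filter_config`.
#' @export
read_problem <- function(model_path, data_path, config_path) {
  spec <- read_model_spec(model_path)
  dataset <- read_data_table(data_path, spec$experiments)
  cfg <- read_run_config(config_path)
  sm <- score_model(dataset, type = cfg$score$type %||% "nll",
                    q = cfg$score$q %||% 0.95)
  problem <- tf_problem(spec$space, spec$catalog, sm, model = spec$model,
                        experiments = spec$experiments)
  chk <- is_viable(problem, cfg$initial_point)
  if (!chk$viable) {
    stop(sprintf("configured initial point is not viable: score %.6g > threshold %.6g",
                 chk$score, sm$s0), call. = FALSE)
  }
  list(problem = problem, init_point = cfg$initial_point,
       filter_config = cfg$filter_config)
}

#' Write filtering results
#'
#' Emits `viable_projections.csv` (one row per discovered reduction, keyed
#' by the sorted projected parameter names joined with `+`),
#' `witnesses.csv` (the witness parameter vector of each reduction),
#' `summary.json` (projection/evaluation/sampling counts) and `run.log`.
#' All writers are deterministic given the result, and each file is
#' written to a temporary name and atomically renamed, so a crash never
#' leaves a half-written table.
#'
#' @param result a `"filter_result"` from [run_filter()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "filter_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  atomically <- function(fname, writer) {
    final <- file.path(out_dir, fname)
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    file.rename(tmp, final)
  }

  recs <- result$records
  proj_df <- if (length(recs) > 0L) {
    do.call(rbind, lapply(recs, function(r) data.frame(
      reduction = r$reduction$id,
      parameters = paste(r$reduction$names, collapse = "+"),
      rank = length(r$reduction$index_set),
      witness_score = r$score,
      phase = r$phase,
      step = r$step,
      maximal = r$reduction$id %in% result$maximal,
      stringsAsFactors = FALSE)))
  } else {
    data.frame(reduction = character(0), parameters = character(0),
               rank = integer(0), witness_score = numeric(0),
               phase = character(0), step = integer(0), maximal = logical(0))
  }
  rownames(proj_df) <- NULL
  atomically("viable_projections.csv", function(p)
    utils::write.csv(proj_df, p, row.names = FALSE))

  wit_df <- if (length(recs) > 0L) {
    cbind(data.frame(reduction = vapply(recs, function(r) r$reduction$id, "")),
          do.call(rbind, lapply(recs, function(r) as.data.frame(t(r$witness)))))
  } else {
    data.frame(reduction = character(0))
  }
  rownames(wit_df) <- NULL
  atomically("witnesses.csv", function(p)
    utils::write.csv(wit_df, p, row.names = FALSE))

  summary <- list(projections_found = length(recs),
                  maximal_reductions = as.list(unname(result$maximal)),
                  evaluations = result$evaluations,
                  samplings = result$samplings,
                  steps = if (is.null(result$steps)) 0L else nrow(result$steps))
  atomically("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE, digits = NA))

  atomically("run.log", function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("topological filtering: %d viable projections, %d evaluations, %d samplings",
                       length(recs), result$evaluations, result$samplings), con)
    if (!is.null(result$steps)) {
      utils::capture.output(print(result$steps), file = con, append = TRUE)
    }
  })
  invisible(out_dir)
}
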