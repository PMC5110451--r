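# End-to-end pipeline: validate -> (optional) learn/update -> exposure
# posterior -> OEL -> hazard quotient -> control band -> heat-map record,
# with stage-labelled errors and a reproducible JSON report.

#' Pipeline run configuration
#'
#' @param network Path to a network JSON file, or a [bn_network()].
#' @param cases Optional path to a case-table CSV (or a data frame) used to
#'   refine the CPTs before inference.
#' @param learn `"em"` (run [em_fit()]), `"update"` (one experience-weighted
#'   [update_with_cases()] pass) or `"none"`; ignored without `cases`.
#' @param evidence Named character vector/list of observed states.
#' @param dose_response Optional [dose_response_config()]. When given, the
#'   OEL enters the hazard quotient as a point mass at [derive_oel()];
#'   otherwise the network's own OEL node posterior is used.
#' @param em List of EM settings (`prior_strength`, `tol`, `max_iter`)
#'   overriding the [em_fit()] defaults.
#' @param seed Integer seed logged with, and used by, every stochastic stage.
#' @param out Optional path for the JSON report.
#' @return A `run_config` object.
#' @export
run_config <- function(network, cases = NULL, learn = c("em", "update", "none"),
                       evidence = NULL, dose_response = NULL, em = list(),
                       seed = 1L, out = NULL) {
  learn <- match.arg(learn)
  if (!is.null(dose_response)) stopifnot(inherits(dose_response, "dose_response_config"))
  structure(list(network = network, cases = cases, learn = learn,
                 evidence = evidence, dose_response = dose_response,
                 em = em, seed = as.integer(seed), out = out),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the 4-step risk pipeline
#'
#' Executes validate -> (optional) EM fit or experience update -> exposure
#' posterior -> OEL derivation -> hazard-quotient forecast -> control band ->
#' heat-map coordinates. Any stage error aborts with a stage-labelled
#' message. The report is reproducible given an identical configuration and
#' seed.
#'
#' @param cfg A [run_config()].
#' @return A `risk_report` list: `mean_hq`, `interval_90`, `band`,
#'   `coordinates` ([heatmap_point()] row), `forecast` (the full
#'   `hq_forecast`), `fit` (if learning ran), `evidence`, `seed`. Written to
#'   `cfg$out` as JSON when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  net <- stage("network", {
    if (inherits(cfg$network, "bn_network")) validate_network(cfg$network)
    else read_network(cfg$network)
  })
  fit <- NULL
  if (!is.null(cfg$cases) && cfg$learn != "none") {
    cases <- stage("cases", {
      if (is.data.frame(cfg$cases)) cfg$cases else read_cases(cfg$cases)
    })
    if (cfg$learn == "em") {
      fit <- stage("learning", do.call(em_fit, c(
        list(net = net, cases = cases, seed = cfg$seed), cfg$em)))
      net <- fit$network
    } else {
      net <- stage("learning", update_with_cases(net, cases))$network
    }
  }
  exposure <- stage("exposure", exposure_posterior(net, cfg$evidence))
  oel <- stage("dose-response", {
    if (!is.null(cfg$dose_response)) point_mass(derive_oel(cfg$dose_response))
    else oel_posterior(net, cfg$evidence)
  })
  forecast <- stage("risk", hazard_quotient(exposure, oel))
  coords <- stage("risk", heatmap_point(forecast))
  report <- structure(list(
    mean_hq = forecast$mean_hq,
    interval_90 = as.list(forecast$interval_90),
    band = as.character(forecast$band),
    mean_concentration = forecast$mean_concentration,
    mean_oel = forecast$mean_oel,
    coordinates = coords,
    forecast = forecast,
    fit = fit,
    evidence = cfg$evidence,
    seed = cfg$seed), class = "risk_report")
  if (!is.null(cfg$out)) {
    stage("report", jsonlite::write_json(list(
      mean_hq = report$mean_hq, interval_90 = report$interval_90,
      band = report$band, mean_concentration = report$mean_concentration,
      mean_oel = report$mean_oel, coordinates = as.list(coords[1, ]),
      evidence = as.list(cfg$evidence), seed = cfg$seed),
      cfg$out, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  report
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> mean HQ ", sprintf("%.1f%%", x$mean_hq),
      " [", sprintf("%.1f", x$interval_90$lo), "-",
      sprintf("%.1f", x$interval_90$hi), "%], band: ", x$band, "\n", sep = "")
  invisible(x)
}

# ---- command-line entry point -------------------------------------------

cli_usage <- "usage: nanoband <command> [options]

commands:
  validate  --network NET.json
  simulate  --material CNT --rows 46 --missing 0.3 --seed 7 --out cases.csv
            [--truth-out NET.json]
  fit       --network NET.json --cases CASES.csv --out FITTED.json
            [--prior 1 --tol 1e-6 --max-iter 200 --seed 1]
  update    --network NET.json --cases CASES.csv --out UPDATED.json
  infer     --network NET.json [--observe VAR=STATE ...] [--out POST.csv]
  risk      --network NET.json [--observe VAR=STATE ...]
            [--pod 1000 --pod-kind NOAEL --uf 100 --cmr yes|no]
            [--out REPORT.json]

exit codes: 0 ok, 2 configuration error, 3 data error, 4 numerical error"

parse_cli_args <- function(args) {
  opts <- list(observe = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'", call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args)) stop("option --", key, " needs a value", call. = FALSE)
    val <- args[[i + 1L]]
    if (key == "observe") {
      kv <- strsplit(val, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("--observe expects VAR=STATE", call. = FALSE)
      opts$observe[kv[1]] <- kv[2]
    } else {
      opts[[gsub("-", "_", key)]] <- val
    }
    i <- i + 2L
  }
  opts
}

cli_fail <- function(code, e) {
  message("error: ", conditionMessage(e))
  code
}

#' Command-line entry point
#'
#' Backs the `inst/cli/nanoband` script; exposed as a function so the
#' subcommands are testable in-process. See the usage string for the
#' available subcommands.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 ok, 2 configuration, 3 data, 4 numerical).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[[1]] %in% c("-h", "--help", "help")) {
    message(cli_usage)
    return(0L)
  }
  cmd <- args[[1]]
  opts <- tryCatch(parse_cli_args(args[-1]),
                   error = function(e) e)
  if (inherits(opts, "error")) return(cli_fail(2L, opts))

  run <- function() {
    switch(cmd,
      validate = {
        net <- read_network(opts$network %||% stop("--network required", call. = FALSE))
        message("ok: ", length(net$variables), " variables, ",
                nrow(net$edges), " edges")
      },
      simulate = {
        fix <- fixture_spec(opts$material %||% "CNT",
                            n_rows = if (!is.null(opts$rows)) as.integer(opts$rows),
                            missing_rate = as.numeric(opts$missing %||% 0.3),
                            seed = as.integer(opts$seed %||% 1))
        write_cases(generate_cases(fix),
                    opts$out %||% stop("--out required", call. = FALSE))
        if (!is.null(opts$truth_out)) write_network(fix$truth, opts$truth_out)
      },
      fit = {
        net <- read_network(opts$network %||% stop("--network required", call. = FALSE))
        fit <- em_fit(net, read_cases(opts$cases %||% stop("--cases required", call. = FALSE)),
                      prior_strength = as.numeric(opts$prior %||% 1),
                      tol = as.numeric(opts$tol %||% 1e-6),
                      max_iter = as.integer(opts$max_iter %||% 200),
                      seed = as.integer(opts$seed %||% 1))
        write_network(fit$network, opts$out %||% stop("--out required", call. = FALSE))
        message("EM: ", fit$iterations, " iterations, ",
                if (fit$converged) "converged" else "not converged")
      },
      update = {
        net <- read_network(opts$network %||% stop("--network required", call. = FALSE))
        upd <- update_with_cases(net, read_cases(opts$cases %||%
                                                   stop("--cases required", call. = FALSE)))
        write_network(upd$network, opts$out %||% stop("--out required", call. = FALSE))
      },
      infer = {
        net <- read_network(opts$network %||% stop("--network required", call. = FALSE))
        post <- posterior_marginals(net, opts$observe)
        if (!is.null(opts$out)) readr::write_csv(post, opts$out)
        else print(as.data.frame(post))
      },
      risk = {
        dr <- if (!is.null(opts$pod)) dose_response_config(
          as.numeric(opts$pod), pod_kind = opts$pod_kind %||% "NOAEL",
          uncertainty_factor = as.numeric(opts$uf %||% 100),
          cmr = identical(opts$cmr, "yes"))
        report <- run_pipeline(run_config(
          network = opts$network %||% stop("--network required", call. = FALSE),
          evidence = if (length(opts$observe)) opts$observe,
          dose_response = dr,
          seed = as.integer(opts$seed %||% 1),
          out = opts$out))
        print(report)
      },
      stop("unknown command '", cmd, "'; run with --help", call. = FALSE))
    0L
  }
  tryCatch(run(), error = function(e) {
    msg <- conditionMessage(e)
    code <- if (grepl("required|unknown command|must be|expects", msg)) 2L
            else if (grepl("file|schema|column|state|case table|network file", msg)) 3L
            else 4L
    cli_fail(code, e)
  })
}
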