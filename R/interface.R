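# Input validation, CSV readers and the end-to-end synthetic-study
# pipeline driver. All file formats are plain CSV; the pipeline manifest
# is JSON.

# Column schemas for every input the pipeline reads. `check` functions
# return a data.frame(row, column, message) of violations.
.schemas <- local({
  num_check <- function(col, test, msg) {
    function(df) {
      bad <- which(!test(df[[col]]))
      if (!length(bad)) return(NULL)
      data.frame(row = bad, column = col, message = msg)
    }
  }
  increasing_within <- function(time_col, group_cols) {
    function(df) {
      key <- if (length(group_cols))
        interaction(df[group_cols], drop = TRUE)
      else factor(rep(1, nrow(df)))
      out <- NULL
      for (idx in split(seq_len(nrow(df)), key)) {
        tt <- df[[time_col]][idx]
        bad <- idx[which(diff(tt) <= 0) + 1L]
        if (length(bad))
          out <- rbind(out, data.frame(
            row = bad, column = time_col,
            message = "times must be strictly increasing within each series"))
      }
      out
    }
  }
  list(
    fluctuation = list(
      columns = c("strain", "replicate", "culture_id", "mutant_count"),
      checks = list(num_check("mutant_count",
                              function(x) is.numeric(x) & !is.na(x) &
                                x >= 0 & x == round(x),
                              "mutant_count must be a non-negative integer"))),
    viable = list(
      columns = c("strain", "replicate", "cfu_per_ml", "volume_ml"),
      checks = list(
        num_check("cfu_per_ml", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "cfu_per_ml must be positive"),
        num_check("volume_ml", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "volume_ml must be positive"))),
    growth = list(
      columns = c("strain", "condition", "replicate", "time_h", "od"),
      checks = list(
        num_check("od", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "od must be positive"),
        increasing_within("time_h", c("strain", "condition", "replicate")))),
    cytometry = list(
      columns = c("strain_pair", "time_point", "fluorescent_events",
                  "nonfluorescent_events", "f_loss"),
      checks = list(
        num_check("fluorescent_events",
                  function(x) is.numeric(x) & !is.na(x) & x >= 0,
                  "fluorescent_events must be >= 0"),
        num_check("nonfluorescent_events",
                  function(x) is.numeric(x) & !is.na(x) & x >= 0,
                  "nonfluorescent_events must be >= 0"),
        num_check("f_loss", function(x) is.numeric(x) & !is.na(x) &
                    x >= 0 & x < 1,
                  "f_loss must lie in [0, 1)"))),
    viability = list(
      columns = c("strain", "replicate", "time_h", "cfu_per_ml"),
      checks = list(
        num_check("cfu_per_ml", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "cfu_per_ml must be positive"),
        increasing_within("time_h", c("strain", "replicate")))),
    livedead = list(
      columns = c("strain", "replicate", "dead_fraction"),
      checks = list(num_check("dead_fraction",
                              function(x) is.numeric(x) & !is.na(x) &
                                x >= 0 & x <= 1,
                              "dead_fraction must lie in [0, 1]"))),
    trajectory = list(
      columns = c("line", "cycle", "tolerance_pct", "rate"),
      checks = list(
        num_check("rate", function(x) is.numeric(x) & !is.na(x) & x >= 0,
                  "rate must be >= 0"),
        increasing_within("cycle", "line"))),
    transfers = list(
      columns = c("line", "cycle", "cfu_i", "cfu_e"),
      checks = list(
        num_check("cfu_i", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "cfu_i must be positive"),
        num_check("cfu_e", function(x) is.numeric(x) & !is.na(x) & x > 0,
                  "cfu_e must be positive"))),
    variants = list(
      columns = c("line", "position", "ref", "alt"),
      checks = list())
  )
})

#' List the column schema of a pipeline input
#'
#' @param schema_name One of `"fluctuation"`, `"viable"`, `"growth"`,
#'   `"cytometry"`, `"viability"`, `"livedead"`, `"trajectory"`,
#'   `"transfers"`, `"variants"`.
#' @return Character vector of required column names.
#' @export
input_schema <- function(schema_name) {
  if (!schema_name %in% names(.schemas))
    stop("unknown schema: ", schema_name,
         " (known: ", paste(names(.schemas), collapse = ", "), ")")
  .schemas[[schema_name]]$columns
}

#' Validate a pipeline input file or data frame
#'
#' Checks that all required columns are present and that every value lies
#' in its domain (counts non-negative, fractions in bounds, times strictly
#' increasing per series). Parse failures are raised as errors (they are
#' not schema violations); schema problems are returned as a violation
#' table.
#'
#' @param x Path to a CSV file, or a data frame.
#' @param schema_name Schema to validate against (see [input_schema()]).
#' @return Data frame with columns `row`, `column`, `message`; zero rows
#'   when the input is valid. Missing columns are reported with `row = NA`.
#' @export
validate_inputs <- function(x, schema_name) {
  schema <- .schemas[[schema_name]]
  if (is.null(schema)) stop("unknown schema: ", schema_name)
  df <- if (is.data.frame(x)) x else {
    if (!file.exists(x)) stop("file not found: ", x)
    tryCatch(read.csv(x, stringsAsFactors = FALSE),
             error = function(e)
               stop("parse error reading ", x, ": ", conditionMessage(e)))
  }
  missing <- setdiff(schema$columns, names(df))
  if (length(missing))
    return(data.frame(row = NA_integer_, column = missing,
                      message = "required column is missing"))
  out <- data.frame(row = integer(), column = character(),
                    message = character())
  for (chk in schema$checks) {
    v <- chk(df)
    if (!is.null(v)) out <- rbind(out, v)
  }
  out
}

stop_if_invalid <- function(x, schema_name, label) {
  v <- validate_inputs(x, schema_name)
  if (nrow(v) > 0)
    stop(sprintf("%s failed %s-schema validation (%d violation(s)); first: %s [column %s%s]",
                 label, schema_name, nrow(v), v$message[1], v$column[1],
                 if (is.na(v$row[1])) "" else sprintf(", row %d", v$row[1])))
  invisible(TRUE)
}

#' Read fluctuation-assay CSV files
#'
#' Reads a mutant-count table and its viable-count companion and assembles
#' one [fluctuation_experiment()] per strain. Calibration CFU/ml values
#' are converted to CFU per culture using `volume_ml`.
#'
#' @param counts_file CSV with columns `strain, replicate, culture_id,
#'   mutant_count`.
#' @param viable_file CSV with columns `strain, replicate, cfu_per_ml,
#'   volume_ml`.
#' @return Named list of `fluctuation_experiment` objects, one per strain.
#' @export
read_fluctuation <- function(counts_file, viable_file) {
  stop_if_invalid(counts_file, "fluctuation", counts_file)
  stop_if_invalid(viable_file, "viable", viable_file)
  counts <- read.csv(counts_file, stringsAsFactors = FALSE)
  viable <- read.csv(viable_file, stringsAsFactors = FALSE)
  strains <- unique(counts$strain)
  out <- lapply(strains, function(s) {
    cc <- counts[counts$strain == s, , drop = FALSE]
    vv <- viable[viable$strain == s, , drop = FALSE]
    if (nrow(vv) == 0) stop("no viable counts for strain ", s)
    fluctuation_experiment(cc$mutant_count,
                           vv$cfu_per_ml * vv$volume_ml,
                           replicate = cc$replicate,
                           culture_volume_ml = vv$volume_ml[1])
  })
  names(out) <- strains
  out
}

#' Default configuration of the synthetic study pipeline
#'
#' One flat list drives both generation and analysis so a whole study can
#' be pinned by a single seed. The per-stage blocks hold the generator
#' truths; see the individual `simulate_*()` functions for the meaning and
#' defaults of each parameter.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested list of class `mutevol_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    fluctuation = list(m = 1, n_cultures = 30, Nt = 2e8),
    growth = list(y0 = -2, yM = 2, SGR = 0.2, LT = 5, noise_cv = 0.02,
                  interval_h = 0.25, duration_h = 50),
    competition = list(true_W = 2, A_start = 0.5, n_rounds = 1,
                       events = 1e5, f_loss = 0.05),
    decay = list(ymax = 1e9, ymin = 1e6, k = 0.1, n_points = 30,
                 duration_h = 90, noise_cv = 0.1),
    trajectory = list(n_cycles = 20, tolerance_start = 5, base_rate = 1e-8,
                      p_step = 0.4, jump_fold = 4, plateau_decline = 0.75)
  ), class = "mutevol_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys not present in the file keep their [default_config()] values.
#'
#' @param path YAML file path.
#' @return A `mutevol_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(user$seed)) user$seed else 1)
  for (block in intersect(names(user), names(cfg))) {
    if (is.list(user[[block]]))
      cfg[[block]][names(user[[block]])] <- user[[block]]
    else cfg[[block]] <- user[[block]]
  }
  cfg
}

#' Run the full synthetic study pipeline
#'
#' Executes generate -> write -> validate -> analyze for all five stages
#' (fluctuation, growth, competition, decay, trajectory), writes per-stage
#' input and result CSVs plus a JSON manifest into `out_dir`, and returns
#' the manifest. A stage failure is isolated: it is recorded in the
#' manifest with its error message and the remaining stages still run.
#'
#' @param config A `mutevol_config` list (see [default_config()]) or a
#'   path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `config$seed`.
#' @return The manifest (named list) invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("mutevol")),
                   seed = config$seed, config = unclass(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    name
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      list(status = "failed", error = conditionMessage(e)))
    if (is.null(res$status)) res$status <- "ok"
    manifest$stages[[name]] <<- res
  }

  run_stage("fluctuation", function() {
    p <- config$fluctuation
    exp <- simulate_fluctuation(p$m, p$n_cultures, Nt = p$Nt,
                                seed = config$seed + 101)
    counts_df <- data.frame(strain = "synthetic",
                            replicate = exp$replicate,
                            culture_id = seq_along(exp$mutant_counts),
                            mutant_count = exp$mutant_counts)
    viable_df <- data.frame(strain = "synthetic", replicate = "R1",
                            cfu_per_ml = exp$viable_counts /
                              exp$culture_volume_ml,
                            volume_ml = exp$culture_volume_ml)
    inp <- c(wcsv(counts_df, "fluctuation.csv"),
             wcsv(viable_df, "viable_counts.csv"))
    est <- mutation_rate(read_fluctuation(
      file.path(out_dir, "fluctuation.csv"),
      file.path(out_dir, "viable_counts.csv"))[[1]])
    out <- wcsv(data.frame(m_hat = est$m_hat, rate = est$rate,
                           ci_low = est$ci_low, ci_high = est$ci_high,
                           n_cultures = est$n_cultures,
                           mean_Nt = est$mean_Nt),
                "mutation_rate.csv")
    list(inputs = inp, outputs = out, true_m = p$m,
         headline = c(m_hat = est$m_hat, rate = est$rate))
  })

  run_stage("growth", function() {
    p <- config$growth
    reps <- lapply(1:3, function(r) {
      g <- simulate_growth(p$y0, p$yM, p$SGR, p$LT, noise_cv = p$noise_cv,
                           interval_h = p$interval_h,
                           duration_h = p$duration_h,
                           seed = config$seed + 200 + r)
      data.frame(strain = "synthetic", condition = "5pct",
                 replicate = paste0("R", r), time_h = g$time_h, od = g$od)
    })
    growth_df <- do.call(rbind, reps)
    inp <- wcsv(growth_df, "growth.csv")
    stop_if_invalid(growth_df, "growth", "growth table")
    summ <- growth_summary(growth_df)
    out <- wcsv(summ, "growth_fits.csv")
    list(inputs = inp, outputs = out, true_SGR = p$SGR,
         headline = c(mean_SGR = mean(summ$SGR, na.rm = TRUE),
                      mean_LT = mean(summ$LT, na.rm = TRUE)))
  })

  run_stage("competition", function() {
    p <- config$competition
    sim <- simulate_competition(p$true_W, p$A_start, p$n_rounds,
                                events = p$events, f_loss = p$f_loss,
                                seed = config$seed + 301)
    cyt <- data.frame(strain_pair = "mutant_vs_ancestor",
                      time_point = sim$round,
                      fluorescent_events = sim$fluorescent,
                      nonfluorescent_events = sim$nonfluorescent,
                      f_loss = sim$f_loss)
    inp <- wcsv(cyt, "cytometry.csv")
    stop_if_invalid(cyt, "cytometry", "cytometry table")
    last <- nrow(cyt)
    est <- estimate_relative_fitness(
      cyt$fluorescent_events[1], cyt$nonfluorescent_events[1],
      cyt$fluorescent_events[last], cyt$nonfluorescent_events[last],
      n = p$n_rounds, f_loss = p$f_loss)
    out <- wcsv(data.frame(A_start = est$A_start, A_end = est$A_end,
                           n = est$n, W = est$W), "fitness.csv")
    list(inputs = inp, outputs = out, true_W = p$true_W,
         headline = c(W = est$W))
  })

  run_stage("decay", function() {
    p <- config$decay
    reps <- lapply(1:3, function(r) {
      d <- simulate_decay(p$ymax, p$ymin, p$k, n_points = p$n_points,
                          duration_h = p$duration_h, noise_cv = p$noise_cv,
                          rise_points = 5, seed = config$seed + 400 + r)
      data.frame(strain = "synthetic", replicate = paste0("R", r),
                 time_h = d$time_h, cfu = d$cfu)
    })
    via <- do.call(rbind, reps)
    names(via)[names(via) == "cfu"] <- "cfu_per_ml"
    inp <- wcsv(via, "viability.csv")
    stop_if_invalid(via, "viability", "viability table")
    ks <- vapply(split(via, via$replicate), function(d) {
      seg <- select_decline_segment(d$time_h, d$cfu_per_ml)
      fit_decay(seg)$coefficients[["k"]]
    }, numeric(1))
    out <- wcsv(data.frame(replicate = names(ks), k = unname(ks)),
                "death_rates.csv")
    list(inputs = inp, outputs = out, true_k = p$k,
         headline = c(mean_k = mean(ks)))
  })

  run_stage("trajectory", function() {
    p <- config$trajectory
    tr <- simulate_trajectory(p$n_cycles, p$tolerance_start, p$base_rate,
                              p_step = p$p_step, jump_fold = p$jump_fold,
                              plateau_decline = p$plateau_decline,
                              seed = config$seed + 501)
    tr_df <- data.frame(line = "E1", cycle = tr$cycle,
                        tolerance_pct = tr$tolerance_pct, rate = tr$rate)
    inp <- wcsv(tr_df, "trajectory.csv")
    stop_if_invalid(tr_df, "trajectory", "trajectory table")
    corr <- delta_correlation(tr_df$tolerance_pct, tr_df$rate,
                              seed = config$seed + 502)
    out <- wcsv(data.frame(rho = corr$rho, p_value = corr$p_value,
                           n_pairs = corr$n_pairs, method = corr$method),
                "delta_correlation.csv")
    list(inputs = inp, outputs = out,
         headline = c(rho = corr$rho, p_value = corr$p_value))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
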