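# Storage-experiment design and synthetic degradation data.

#' Build a factorial storage-experiment design
#'
#' Crosses storage temperatures with seed water-activity levels to produce one
#' storage experiment per condition. Experiment duration follows the bulk
#' storage convention used throughout the package: 72 days for
#' \eqn{a_w \le 0.81} (slow spoilage regime) and 48 days for wetter seed
#' (\eqn{a_w > 0.81}), where fungal activity shortens the useful observation
#' window. Selected conditions can be earmarked as independent validation
#' experiments; the remaining experiments form the model-building set.
#'
#' @param temperatures Numeric vector of storage temperatures in degrees
#'   Celsius (design range 12--30).
#' @param water_activities Numeric vector of seed water activities, fractions
#'   in (0, 1) (design range 0.75--0.90).
#' @param sampling_interval Days between successive phytosterol determinations
#'   (default 6).
#' @param replicates Number of replicate determinations at each sampling time
#'   (default 3, i.e. triplicate analyses).
#' @param validation_conditions Optional list of `c(temperature, water_activity)`
#'   pairs (or a 2-column matrix, rows `(T, a_w)`) marking experiments whose
#'   data are reserved for external validation. Each pair must occur in the
#'   crossed design.
#' @return A `storage_design` object: a data frame of experiments with columns
#'   `experiment_id`, `temperature_C`, `water_activity`, `duration_days`,
#'   `purpose` (`"build"` or `"validation"`), carrying `sampling_interval` and
#'   `replicates` as attributes.
#' @examples
#' d <- build_storage_design()
#' table(d$purpose)   # 12 build + 4 validation
#' @seealso [simulate_degradation()], [sampling_times()]
#' @export
build_storage_design <- function(temperatures = c(12, 18, 24, 30),
                                 water_activities = c(0.75, 0.80, 0.85, 0.90),
                                 sampling_interval = 6,
                                 replicates = 3,
                                 validation_conditions = default_validation_conditions()) {
  if (length(temperatures) == 0L || length(water_activities) == 0L) {
    stop("'temperatures' and 'water_activities' must be non-empty")
  }
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 1L ||
      sampling_interval <= 0) {
    stop("'sampling_interval' must be a single positive number of days")
  }
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1) {
    stop("'replicates' must be >= 1")
  }
  if (any(water_activities <= 0 | water_activities >= 1)) {
    stop("water activities must lie strictly in (0, 1)")
  }

  grid <- expand.grid(temperature_C = temperatures,
                      water_activity = water_activities,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$temperature_C, grid$water_activity), , drop = FALSE]
  rownames(grid) <- NULL

  purpose <- rep("build", nrow(grid))
  if (!is.null(validation_conditions)) {
    vc <- normalize_conditions(validation_conditions)
    for (i in seq_len(nrow(vc))) {
      hit <- which(abs(grid$temperature_C - vc[i, 1L]) < 1e-9 &
                   abs(grid$water_activity - vc[i, 2L]) < 1e-9)
      if (length(hit) == 0L) {
        stop(sprintf("validation condition (T = %g, aw = %g) is not in the crossed design",
                     vc[i, 1L], vc[i, 2L]))
      }
      purpose[hit] <- "validation"
    }
  }

  design <- data.frame(
    experiment_id = sprintf("E%02d", seq_len(nrow(grid))),
    temperature_C = grid$temperature_C,
    water_activity = grid$water_activity,
    duration_days = storage_duration(grid$water_activity),
    purpose = purpose,
    stringsAsFactors = FALSE
  )
  structure(design,
            sampling_interval = sampling_interval,
            replicates = as.integer(replicates),
            class = c("storage_design", "data.frame"))
}

#' Default validation conditions
#'
#' One condition per temperature is held out for external validation,
#' mirroring the usual one-V-per-temperature layout of a 4 x 4 storage trial.
#' @return A 4 x 2 matrix with columns temperature and water activity.
#' @export
default_validation_conditions <- function() {
  rbind(c(12, 0.85), c(18, 0.80), c(24, 0.85), c(30, 0.80))
}

#' Storage design with per-temperature water-activity levels
#'
#' The `"rounded"` preset crosses the four canonical levels
#' \{0.75, 0.80, 0.85, 0.90\}; the `"exact"` preset uses the slightly
#' different per-temperature levels realised in practice when water activity
#' is set with saturated salt solutions (e.g. 0.76/0.80/0.86/0.90 at 12 and
#' 18 degrees C). In the exact preset the design is no longer a pure cross,
#' so experiments are assembled per temperature.
#'
#' @param preset `"rounded"` or `"exact"`.
#' @inheritParams build_storage_design
#' @return A `storage_design` object.
#' @export
storage_design_preset <- function(preset = c("rounded", "exact"),
                                  sampling_interval = 6, replicates = 3) {
  preset <- match.arg(preset)
  if (preset == "rounded") {
    return(build_storage_design(sampling_interval = sampling_interval,
                                replicates = replicates))
  }
  # per-temperature aw levels and validation flags
  levels <- list(
    `12` = list(aw = c(0.76, 0.80, 0.86, 0.90), v = c(FALSE, FALSE, TRUE, FALSE)),
    `18` = list(aw = c(0.76, 0.80, 0.86, 0.90), v = c(FALSE, TRUE, FALSE, FALSE)),
    `24` = list(aw = c(0.75, 0.81, 0.85, 0.90), v = c(FALSE, FALSE, TRUE, FALSE)),
    `30` = list(aw = c(0.75, 0.80, 0.84, 0.90), v = c(FALSE, TRUE, FALSE, FALSE))
  )
  rows <- do.call(rbind, lapply(names(levels), function(tt) {
    lv <- levels[[tt]]
    data.frame(temperature_C = as.numeric(tt), water_activity = lv$aw,
               purpose = ifelse(lv$v, "validation", "build"),
               stringsAsFactors = FALSE)
  }))
  design <- data.frame(
    experiment_id = sprintf("E%02d", seq_len(nrow(rows))),
    temperature_C = rows$temperature_C,
    water_activity = rows$water_activity,
    duration_days = storage_duration(rows$water_activity),
    purpose = rows$purpose,
    stringsAsFactors = FALSE
  )
  structure(design,
            sampling_interval = sampling_interval,
            replicates = as.integer(replicates),
            class = c("storage_design", "data.frame"))
}

# 72-day series for aw <= 0.81, 48-day series for wetter seed.
storage_duration <- function(water_activity) {
  ifelse(water_activity <= 0.81, 72, 48)
}

#' Sampling times of one experiment
#'
#' @param duration_days Experiment duration.
#' @param sampling_interval Days between determinations.
#' @return Numeric vector `0, interval, 2 interval, ...` up to and including
#'   the duration (the duration itself is included only when the interval
#'   divides it).
#' @export
sampling_times <- function(duration_days, sampling_interval) {
  seq(0, duration_days, by = sampling_interval)
}

normalize_conditions <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x[, 1:2]))
  do.call(rbind, lapply(x, function(p) matrix(as.numeric(p[1:2]), 1L)))
}

#' @export
print.storage_design <- function(x, ...) {
  cat(sprintf("Storage design: %d experiments (%d build, %d validation)\n",
              nrow(x), sum(x$purpose == "build"), sum(x$purpose == "validation")))
  cat(sprintf("Sampling every %g days, %d replicate(s) per time point\n",
              attr(x, "sampling_interval"), attr(x, "replicates")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Simulate a phytosterol degradation dataset
#'
#' Evaluates the quadratic degradation surface at every (condition, time)
#' point of the design and adds independent Gaussian measurement noise to
#' each replicate, emulating triplicate chromatographic determinations of the
#' total phytosterol content (mg per g of seed). Rows from experiments marked
#' `validation` receive role `"validation"`; build rows start `"unassigned"`
#' and are split later by [split_learning_test()].
#'
#' @param design A `storage_design`.
#' @param coefficients Surface coefficients, default
#'   [reference_rsr_coefficients()].
#' @param noise_sd Standard deviation of the additive measurement noise in
#'   mg g\eqn{^{-1}} (default 0.1, commensurate with a validation RMSE of
#'   about 0.14).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `degradation_dataset`: a data frame with columns
#'   `experiment_id`, `temperature_C`, `water_activity`, `time_days`,
#'   `replicate`, `ps_mg_per_g`, `role`.
#' @examples
#' d <- build_storage_design()
#' ds <- simulate_degradation(d, noise_sd = 0, seed = 1)
#' range(ds$ps_mg_per_g)
#' @export
simulate_degradation <- function(design,
                                 coefficients = reference_rsr_coefficients(),
                                 noise_sd = 0.1,
                                 seed = 1L) {
  stopifnot(inherits(design, "storage_design"))
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  interval <- attr(design, "sampling_interval")
  reps <- attr(design, "replicates")

  rows <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    times <- sampling_times(design$duration_days[i], interval)
    expand.grid(time_days = times, replicate = seq_len(reps),
                KEEP.OUT.ATTRS = FALSE)[, c("time_days", "replicate")] |>
      transform(experiment_id = design$experiment_id[i],
                temperature_C = design$temperature_C[i],
                water_activity = design$water_activity[i],
                role = ifelse(design$purpose[i] == "validation",
                              "validation", "unassigned"))
  }))
  rows <- rows[order(rows$experiment_id, rows$time_days, rows$replicate), ]
  rownames(rows) <- NULL

  surface <- predict_rsr(coefficients, rows)
  if (any(surface <= 0)) {
    bad <- which.min(surface)
    stop(sprintf(paste0("degradation surface is non-positive (%.4f mg/g) at ",
                        "(aw = %g, T = %g, tau = %g): design lies outside the ",
                        "model's validity region"),
                 surface[bad], rows$water_activity[bad],
                 rows$temperature_C[bad], rows$time_days[bad]))
  }

  ps <- with_seed(seed, surface + stats::rnorm(length(surface), 0, noise_sd))
  ps <- pmax(ps, PS_FLOOR)

  out <- data.frame(
    experiment_id = rows$experiment_id,
    temperature_C = rows$temperature_C,
    water_activity = rows$water_activity,
    time_days = rows$time_days,
    replicate = as.integer(rows$replicate),
    ps_mg_per_g = ps,
    role = rows$role,
    stringsAsFactors = FALSE
  )
  as_degradation_dataset(out, seed = seed)
}

# Truncation floor keeping PS strictly positive, required by the
# relative/log-scale validation metrics.
PS_FLOOR <- 1e-6

#' Coerce a data frame to a degradation dataset
#'
#' Validates the measurement-table schema used throughout the package.
#'
#' @param x Data frame with columns `experiment_id`, `temperature_C`,
#'   `water_activity`, `time_days`, `replicate`, `ps_mg_per_g` and optionally
#'   `role` (defaults to `"unassigned"`).
#' @param seed Optional generator seed recorded as metadata.
#' @return A `degradation_dataset`.
#' @export
as_degradation_dataset <- function(x, seed = NULL) {
  needed <- c("experiment_id", "temperature_C", "water_activity",
              "time_days", "replicate", "ps_mg_per_g")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("missing dataset columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(x$role)) x$role <- "unassigned"
  bad_role <- setdiff(unique(x$role),
                      c("learning", "test", "validation", "unassigned"))
  if (length(bad_role)) stop("unknown roles: ", paste(bad_role, collapse = ", "))
  if (any(x$ps_mg_per_g <= 0)) stop("phytosterol content must be > 0 in every row")
  if (any(x$water_activity <= 0 | x$water_activity >= 1)) {
    stop("water activity must lie strictly in (0, 1)")
  }
  if (any(x$time_days < 0)) stop("storage time must be >= 0")
  structure(as.data.frame(x, stringsAsFactors = FALSE),
            seed = seed,
            class = c("degradation_dataset", "data.frame"))
}

#' Assign learning/test roles to the model-building rows
#'
#' Splits the building data (rows whose role is `"unassigned"`) into a
#' learning set used to fit models and a test set used to monitor training.
#' Replicate determinations of the same sampling point (same experiment and
#' time) are kept together so that near-identical measurements cannot leak
#' across the split; the learning set receives `floor(fraction * n_groups)`
#' sampling points, the test set the remainder. With the canonical 117
#' triplicate sampling points this reproduces the 243/108 learning/test split
#' of a 351-row building set at a 70:30 ratio. Validation rows are untouched.
#'
#' @param dataset A `degradation_dataset` with unassigned build rows.
#' @param learning_fraction Fraction of building sampling points assigned to
#'   the learning set, in (0, 1] (default 0.7).
#' @param seed Integer seed for the random assignment.
#' @return The dataset with roles filled in.
#' @export
split_learning_test <- function(dataset, learning_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  if (!is.numeric(learning_fraction) || learning_fraction <= 0 ||
      learning_fraction > 1) {
    stop("'learning_fraction' must lie in (0, 1]")
  }
  build <- which(dataset$role == "unassigned")
  if (length(build) == 0L) {
    stop("roles already assigned: no unassigned building rows to split")
  }
  key <- paste(dataset$experiment_id[build], dataset$time_days[build])
  groups <- unique(key)
  n_learn <- floor(learning_fraction * length(groups))
  learn_groups <- with_seed(seed, sample(groups, n_learn))
  dataset$role[build] <- ifelse(key %in% learn_groups, "learning", "test")
  attr(dataset, "split_seed") <- seed
  dataset
}

#' Role shares of a fully assigned dataset
#'
#' @param dataset A `degradation_dataset` with every row assigned a role.
#' @return Named numeric vector of the learning, test and validation
#'   fractions; sums to 1.
#' @export
set_shares <- function(dataset) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  if (any(dataset$role == "unassigned")) {
    stop("all rows must be role-assigned before computing shares")
  }
  n <- nrow(dataset)
  c(learning = sum(dataset$role == "learning") / n,
    test = sum(dataset$role == "test") / n,
    validation = sum(dataset$role == "validation") / n)
}

#' @export
print.degradation_dataset <- function(x, ...) {
  cat(sprintf("Degradation dataset: %d measurements, %d experiments\n",
              nrow(x), length(unique(x$experiment_id))))
  cat("Roles:", paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                      collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write a degradation dataset as CSV
#'
#' The on-disk schema is one row per measurement:
#' `experiment_id,temperature_C,water_activity,time_days,replicate,ps_mg_per_g,role`
#' (UTF-8, dot decimal separator).
#'
#' @param dataset A `degradation_dataset`.
#' @param path File path.
#' @return `read_degradation_csv` returns a `degradation_dataset`;
#'   `write_degradation_csv` returns `path` invisibly.
#' @export
write_degradation_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_degradation_csv
#' @export
read_degradation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_degradation_dataset(df)
}

# Run code with a temporary RNG state so simulation seeds do not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
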