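#' @keywords internal
"_PACKAGE"

# Canonical trait vocabulary for plot-level records. grain_yield_t_ha is
# derived (see derive_yields()), the rest are measured in the field.
TRAIT_VOCAB <- c(
  "stem_diameter_mm", "ear_height_m", "plant_height_m",
  "rows_per_ear", "grains_per_row", "grains_per_ear",
  "ear_weight_kg", "grain_moisture_pct", "grain_yield_t_ha"
)
COUNT_TRAITS <- c("rows_per_ear", "grains_per_row", "grains_per_ear")
ID_COLUMNS <- c("environment", "genotype", "replicate")
MATERIAL_CLASSES <- c("single_cross", "double_cross", "national_hybrid",
                      "composite")

# classed conditions so callers can distinguish failure modes
abort_mm <- function(message, class) {
  stop(structure(
    class = c(paste0("maizemet_", class), "maizemet_error", "error",
              "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Plot configuration for yield standardization
#'
#' Bundles the constants needed to convert plot ear weight to grain yield in
#' tons per hectare: net harvested plot area, reference grain moisture, and
#' the shelling coefficient (fraction of ear weight that is grain).
#'
#' @param npa_m2 Net harvested plot area in square metres (> 0). There is no
#'   universal default: it depends on the trial's harvest protocol.
#' @param hr_pct Reference moisture content in percent, default 15.
#' @param shelling Shelling coefficient in (0, 1], default 0.8.
#' @return A `plot_config` list with the three validated fields.
#' @examples
#' plot_config(npa_m2 = 8)
#' @export
plot_config <- function(npa_m2, hr_pct = 15, shelling = 0.8) {
  if (!is.numeric(npa_m2) || length(npa_m2) != 1 || !is.finite(npa_m2) ||
      npa_m2 <= 0) {
    abort_mm("`npa_m2` must be a single finite number > 0", "domain_error")
  }
  if (!is.numeric(hr_pct) || length(hr_pct) != 1 || !is.finite(hr_pct) ||
      hr_pct < 0 || hr_pct >= 100) {
    abort_mm("`hr_pct` must be in [0, 100)", "domain_error")
  }
  if (!is.numeric(shelling) || length(shelling) != 1 ||
      !is.finite(shelling) || shelling <= 0 || shelling > 1) {
    abort_mm("`shelling` must be in (0, 1]", "domain_error")
  }
  structure(list(npa_m2 = npa_m2, hr_pct = hr_pct, shelling = shelling),
            class = "plot_config")
}

#' Assemble a validated multi-environment trial dataset
#'
#' The central container of the package: long-format plot observations (one
#' row per plot, one column per trait) plus genotype and environment
#' registries and the plot configuration. Registries are auto-built from the
#' distinct labels in `observations` when not supplied.
#'
#' @param observations Data frame with columns `environment`, `genotype`,
#'   `replicate` and any subset of the canonical trait columns (see
#'   [trait_vocabulary()]). Missing trait values are `NA`, never zero.
#' @param genotypes Optional registry data frame with columns `code`,
#'   `designation`, `material_class`, `origin`.
#' @param environments Optional registry data frame with column `name` and
#'   optional weather metadata (`temp_c`, `rainfall_mm`, `rainy_days`,
#'   `humidity_pct`).
#' @param plot_config A [plot_config()] object. Required: the net plot area
#'   has no defensible default and must come from the harvest protocol.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(observations, genotypes = NULL,
                          environments = NULL, plot_config) {
  if (!inherits(plot_config, "plot_config")) {
    abort_mm("`plot_config` must be created with plot_config()",
             "domain_error")
  }
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ID_COLUMNS, names(observations))
  if (length(missing_cols) > 0) {
    abort_mm(sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")), "format_error")
  }
  for (col in ID_COLUMNS) {
    observations[[col]] <- as.character(observations[[col]])
  }
  trait_cols <- intersect(TRAIT_VOCAB, names(observations))
  key <- do.call(paste, c(observations[ID_COLUMNS], sep = "\r"))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort_mm(sprintf(
      "duplicate (environment, genotype, replicate) triple(s): %s",
      paste(gsub("\r", ", ", dups), collapse = "; ")), "integrity_error")
  }
  for (tr in trait_cols) {
    v <- observations[[tr]]
    if (!is.numeric(v)) {
      abort_mm(sprintf("trait column `%s` is not numeric", tr),
               "format_error")
    }
    bad <- !is.na(v) & !is.finite(v)
    if (any(bad)) {
      abort_mm(sprintf("trait `%s` has non-finite value(s) in row(s) %s",
                       tr, paste(which(bad), collapse = ", ")),
               "domain_error")
    }
  }
  viol <- range_violations(observations, trait_cols)
  if (nrow(viol) > 0) {
    abort_mm(sprintf(
      "trait value(s) out of range: %s",
      paste(sprintf("%s row %d (%g)", viol$trait, viol$row, viol$value),
            collapse = "; ")), "domain_error")
  }
  if (is.null(genotypes)) {
    codes <- sort(unique(observations$genotype))
    genotypes <- data.frame(code = codes,
                            designation = rep(NA_character_,
                                              length(codes)),
                            material_class = rep(NA_character_,
                                                 length(codes)),
                            origin = rep(NA_character_, length(codes)),
                            stringsAsFactors = FALSE)
  } else {
    genotypes <- validate_genotype_registry(genotypes)
  }
  if (is.null(environments)) {
    environments <- data.frame(name = sort(unique(observations$environment)),
                               stringsAsFactors = FALSE)
  } else {
    environments <- validate_environment_registry(environments)
  }
  unknown_g <- setdiff(unique(observations$genotype), genotypes$code)
  if (length(unknown_g) > 0) {
    abort_mm(sprintf("genotype(s) not in registry: %s",
                     paste(unknown_g, collapse = ", ")), "integrity_error")
  }
  unknown_e <- setdiff(unique(observations$environment), environments$name)
  if (length(unknown_e) > 0) {
    abort_mm(sprintf("environment(s) not in registry: %s",
                     paste(unknown_e, collapse = ", ")), "integrity_error")
  }
  rownames(observations) <- NULL
  structure(list(observations = observations, genotypes = genotypes,
                 environments = environments, plot_config = plot_config),
            class = "trial_dataset")
}

#' Canonical trait vocabulary
#'
#' @return Character vector of the trait column names the package recognises.
#' @export
trait_vocabulary <- function() TRAIT_VOCAB

range_violations <- function(observations, trait_cols) {
  out <- data.frame(trait = character(), row = integer(), value = double())
  check <- function(trait, bad_fun) {
    if (!trait %in% trait_cols) return()
    v <- observations[[trait]]
    bad <- which(!is.na(v) & bad_fun(v))
    if (length(bad) > 0) {
      out <<- rbind(out, data.frame(trait = trait, row = bad,
                                    value = v[bad]))
    }
  }
  for (tr in COUNT_TRAITS) check(tr, function(v) v < 0)
  check("ear_weight_kg", function(v) v < 0)
  check("grain_moisture_pct", function(v) v < 0 | v >= 100)
  out
}

validate_genotype_registry <- function(genotypes) {
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  need <- c("code", "designation", "material_class", "origin")
  missing_cols <- setdiff(need, names(genotypes))
  if (length(missing_cols) > 0) {
    abort_mm(sprintf("genotype registry missing column(s): %s",
                     paste(missing_cols, collapse = ", ")), "format_error")
  }
  if (anyDuplicated(genotypes$code)) {
    abort_mm("genotype registry codes are not unique", "integrity_error")
  }
  bad <- !is.na(genotypes$material_class) &
    !genotypes$material_class %in% MATERIAL_CLASSES
  if (any(bad)) {
    abort_mm(sprintf("unknown material_class: %s (allowed: %s)",
                     paste(unique(genotypes$material_class[bad]),
                           collapse = ", "),
                     paste(MATERIAL_CLASSES, collapse = ", ")),
             "domain_error")
  }
  genotypes[need]
}

validate_environment_registry <- function(environments) {
  environments <- as.data.frame(environments, stringsAsFactors = FALSE)
  if (!"name" %in% names(environments)) {
    abort_mm("environment registry missing column `name`", "format_error")
  }
  if (anyDuplicated(environments$name)) {
    abort_mm("environment registry names are not unique", "integrity_error")
  }
  for (col in c("rainfall_mm", "rainy_days", "humidity_pct")) {
    if (col %in% names(environments)) {
      v <- environments[[col]]
      if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
        abort_mm(sprintf("environment weather field `%s` must be finite and non-negative",
                         col), "domain_error")
      }
    }
  }
  environments
}

# Accepts both "." and "," decimal separators; returns NA for empty cells
# and signals a parse error (with row numbers) for anything non-numeric.
parse_numeric_column <- function(x, column) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort_mm(sprintf("non-numeric value in column `%s`, data row(s) %s",
                     column, paste(bad, collapse = ", ")), "parse_error")
  }
  out
}

#' Read a long-format trial CSV
#'
#' Expects one row per plot with columns `environment,genotype,replicate`
#' followed by trait columns drawn from [trait_vocabulary()]. Decimal
#' separators "." and "," are both accepted; empty cells are missing values.
#' Unknown trait columns are preserved with a warning. Registries are built
#' from the distinct labels unless registry CSVs are supplied.
#'
#' @param path Path to the trial CSV.
#' @param plot_config A [plot_config()] object.
#' @param genotypes_path,environments_path Optional registry CSV paths
#'   (columns `code,designation,material_class,origin` and
#'   `name,temp_c,rainfall_mm,rainy_days,humidity_pct`).
#' @return A validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, plot_config, genotypes_path = NULL,
                           environments_path = NULL) {
  if (!file.exists(path)) {
    abort_mm(sprintf("file not found: %s", path), "io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(ID_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_mm(sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")), "format_error")
  }
  extra <- setdiff(names(raw), c(ID_COLUMNS, TRAIT_VOCAB))
  if (length(extra) > 0) {
    warning(sprintf("unknown trait column(s) preserved: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(names(raw), ID_COLUMNS)) {
    raw[[col]] <- parse_numeric_column(raw[[col]], col)
  }
  if (nrow(raw) == 0) {
    warning("trial file contains a header but no observations",
            call. = FALSE)
  }
  genotypes <- if (!is.null(genotypes_path)) {
    utils::read.csv(genotypes_path, colClasses = "character",
                    strip.white = TRUE)
  }
  environments <- if (!is.null(environments_path)) {
    env <- utils::read.csv(environments_path, colClasses = "character",
                           strip.white = TRUE)
    for (col in intersect(c("temp_c", "rainfall_mm", "rainy_days",
                            "humidity_pct"), names(env))) {
      env[[col]] <- parse_numeric_column(env[[col]], col)
    }
    env
  }
  trial_dataset(raw, genotypes = genotypes, environments = environments,
                plot_config = plot_config)
}

#' Write a trial dataset to CSV
#'
#' Emits the long layout accepted by [read_trial_csv()], "." as the decimal
#' separator, missing trait values as empty cells. The written file
#' round-trips: reading it back reproduces the observations exactly (values
#' are serialized at full double precision).
#'
#' @param dataset A [trial_dataset()].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  obs <- dataset$observations
  out <- obs[ID_COLUMNS]
  for (tr in intersect(TRAIT_VOCAB, names(obs))) {
    v <- obs[[tr]]
    out[[tr]] <- ifelse(is.na(v), "",
                        formatC(v, digits = 17, format = "g"))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_mm(sprintf("cannot write to %s", path), "io_error")
  invisible(path)
}

#' Check an assembled dataset against the trial design
#'
#' A pure reporting operation: for every environment it lists the genotypes
#' present, the replicate count per genotype, a balance flag (every present
#' genotype observed once in each replicate of that environment), genotypes
#' absent from that environment, and any trait range violations. The dataset
#' is never modified.
#'
#' @param dataset A [trial_dataset()].
#' @return A `validation_report` list with elements `per_environment`
#'   (data frame: environment, genotype, n_replicates, complete),
#'   `balance` (named logical per environment), `absent` (data frame:
#'   environment, genotype for registry genotypes unobserved there) and
#'   `range_violations`.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  obs <- dataset$observations
  envs <- unique(obs$environment)
  per_env <- data.frame(environment = character(), genotype = character(),
                        n_replicates = integer(), complete = logical())
  balance <- logical(0)
  absent <- data.frame(environment = character(), genotype = character())
  for (env in envs) {
    sub <- obs[obs$environment == env, ]
    r <- length(unique(sub$replicate))
    counts <- table(sub$genotype)
    per_env <- rbind(per_env, data.frame(
      environment = env, genotype = names(counts),
      n_replicates = as.integer(counts),
      complete = as.integer(counts) == r))
    balance[env] <- all(counts == r)
    miss <- setdiff(dataset$genotypes$code, names(counts))
    if (length(miss) > 0) {
      absent <- rbind(absent,
                      data.frame(environment = env, genotype = miss))
    }
  }
  rownames(per_env) <- NULL
  structure(list(per_environment = per_env, balance = balance,
                 absent = absent,
                 range_violations = range_violations(
                   obs, intersect(TRAIT_VOCAB, names(obs)))),
            class = "validation_report")
}

#' Restrict a dataset to one environment
#'
#' @param dataset A [trial_dataset()].
#' @param environment_id Environment name; must exist in the dataset.
#' @return A [trial_dataset()] holding only that environment's observations,
#'   with registries filtered to the labels that remain.
#' @export
subset_by_environment <- function(dataset, environment_id) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!environment_id %in% dataset$environments$name) {
    abort_mm(sprintf("unknown environment: %s", environment_id),
             "lookup_error")
  }
  obs <- dataset$observations[
    dataset$observations$environment == environment_id, , drop = FALSE]
  trial_dataset(
    obs,
    genotypes = dataset$genotypes[
      dataset$genotypes$code %in% obs$genotype, , drop = FALSE],
    environments = dataset$environments[
      dataset$environments$name == environment_id, , drop = FALSE],
    plot_config = dataset$plot_config)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "trial_dataset: %d plot observations, %d genotypes, %d environments\n",
    nrow(x$observations), nrow(x$genotypes), nrow(x$environments)))
  traits <- intersect(TRAIT_VOCAB, names(x$observations))
  cat("traits:", paste(traits, collapse = ", "), "\n")
  cat(sprintf("plot config: NPA %.3g m2, Hr %.3g%%, shelling %.3g\n",
              x$plot_config$npa_m2, x$plot_config$hr_pct,
              x$plot_config$shelling))
  invisible(x)
}
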