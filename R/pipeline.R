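#' Run configuration for the end-to-end pipeline
#'
#' Bundles the per-genotype inputs (synthetic presets or TIFF paths) with
#' the stage configurations and a single global seed. The global seed fans
#' out to fixed child seeds per stage (scene generation, Costes scrambles,
#' bootstrap intervals) so each stage is independently reproducible.
#'
#' @param groups named list (one entry per genotype). Each element is
#'   either a [synthetic_config()] or a list
#'   `list(path = <tiff path(s)>, channel_roles = <roles>)` for measured
#'   data. Exactly one of the two forms per group.
#' @param segmentation a [segmentation_config()].
#' @param chromatin a [chromatin_config()].
#' @param costes a [costes_config()], or `NULL` to skip Costes testing.
#' @param voxel_size `(dz, dy, dx)` in um, used for file inputs.
#' @param seed global integer seed.
#' @param out_dir optional output directory; when given, per-nucleus,
#'   profile, colocalization and comparison CSVs plus a JSON run summary
#'   are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(groups = list(
                         Wt = genotype_preset("Wt"),
                         TrJ = genotype_preset("TrJ")
                       ),
                       segmentation = segmentation_config(),
                       chromatin = chromatin_config(),
                       costes = costes_config(),
                       voxel_size = c(1.00, 0.379, 0.379),
                       seed = 1L,
                       out_dir = NULL) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list (one entry per genotype).")
  }
  for (g in groups) {
    ok <- inherits(g, "synthetic_config") ||
      (is.list(g) && !is.null(g$path) && !is.null(g$channel_roles))
    if (!ok) {
      abort(paste(
        "Each group must be a synthetic_config or a",
        "list(path=, channel_roles=)."
      ))
    }
  }
  structure(
    list(
      groups = groups, segmentation = segmentation, chromatin = chromatin,
      costes = costes, voxel_size = voxel_size, seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors [run_config()]: a `groups` mapping where each entry has
#' either `preset: Wt|TrJ` (plus optional [synthetic_config()] overrides)
#' or `path:` and `channel_roles:`; optional `segmentation`, `chromatin`,
#' `costes` mappings of config overrides; `seed`; `out_dir`; `voxel_size`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$groups)) abort("Config must declare `groups`.")
  groups <- lapply(raw$groups, function(g) {
    if (!is.null(g$preset)) {
      preset <- g$preset
      g$preset <- NULL
      do.call(genotype_preset, c(list(name = preset), g))
    } else {
      g
    }
  })
  args <- list(groups = groups)
  if (!is.null(raw$segmentation)) {
    args$segmentation <- do.call(segmentation_config, raw$segmentation)
  }
  if (!is.null(raw$chromatin)) {
    args$chromatin <- do.call(chromatin_config, raw$chromatin)
  }
  if (!is.null(raw$costes)) {
    args$costes <- do.call(costes_config, raw$costes)
  }
  if (!is.null(raw$voxel_size)) args$voxel_size <- raw$voxel_size
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  do.call(run_config, args)
}

# analysis of one group's stack: records + profiles + coloc
analyse_stack <- function(stack, genotype, cfg, group_index) {
  labels <- segment_nuclei(stack, cfg$segmentation)
  n <- max(labels)
  if (n == 0L) {
    abort(sprintf("Stage segment: no nuclei found in group %s.", genotype))
  }
  records <- measure_nuclei(stack, labels)
  records <- dplyr::mutate(records, genotype = genotype, .after = "label")

  roles <- stack$channel_roles[!is.na(stack$channel_roles)]
  prof_rows <- list()
  coloc_rows <- list()
  for (lab in seq_len(n)) {
    crop <- crop_nucleus(stack, labels, lab)
    masks <- chromatin_masks(crop, cfg$chromatin)
    for (role in roles) {
      pr <- peripheral_central_summary(crop, role)
      pr <- dplyr::select(pr, -"peripheral_values", -"central_values")
      prof_rows[[length(prof_rows) + 1L]] <-
        dplyr::mutate(pr, label = lab, genotype = genotype, .before = 1)
    }
    ccfg <- cfg$costes
    if (!is.null(ccfg)) {
      ccfg$seed <- child_seed(cfg$seed, 100L * group_index + lab)
    }
    cl <- coloc_pairings(crop, masks, cfg$chromatin, ccfg)
    if (nrow(cl)) {
      coloc_rows[[length(coloc_rows) + 1L]] <-
        dplyr::mutate(cl, genotype = genotype, .after = "label")
    }
  }
  list(
    nuclei = records,
    profiles = dplyr::bind_rows(prof_rows),
    coloc = dplyr::bind_rows(coloc_rows)
  )
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> segment -> classify -> profile -> colocalize ->
#' compare, from one configuration. Identical configuration and seed give
#' identical outputs.
#'
#' @param cfg a [run_config()].
#' @return A `nucoloc_run` list: `nuclei` (per-nucleus records),
#'   `profiles` (peripheral/central summaries), `coloc` (per-nucleus
#'   pairing coefficients), `comparisons` (between-group tests for volume,
#'   channel means and coefficients; `NULL` unless exactly two groups), and
#'   `summary` (config echo and per-stage counts). With `out_dir` set, the
#'   tables are written as CSV and the summary as JSON.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) abort("`cfg` must be a run_config.")
  results <- vector("list", length(cfg$groups))
  for (i in seq_along(cfg$groups)) {
    gname <- names(cfg$groups)[i]
    g <- cfg$groups[[i]]
    if (inherits(g, "synthetic_config")) {
      g$seed <- child_seed(cfg$seed, i)
      scene <- generate_scene(g)
      stack <- scene$stack
    } else {
      stack <- read_stack(g$path, g$channel_roles, cfg$voxel_size)
    }
    results[[i]] <- analyse_stack(stack, gname, cfg, i)
  }
  nuclei <- dplyr::bind_rows(lapply(results, `[[`, "nuclei"))
  profiles <- dplyr::bind_rows(lapply(results, `[[`, "profiles"))
  coloc <- dplyr::bind_rows(lapply(results, `[[`, "coloc"))

  comparisons <- NULL
  if (length(cfg$groups) == 2L) {
    comparisons <- compare_all(nuclei, profiles, coloc,
      ref = names(cfg$groups)[1], seed = cfg$seed
    )
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("nucoloc")),
    seed = cfg$seed,
    groups = lapply(seq_along(cfg$groups), function(i) {
      list(
        name = names(cfg$groups)[i],
        n_nuclei = sum(nuclei$genotype == names(cfg$groups)[i])
      )
    }),
    n_pairings = length(unique(coloc$pairing)),
    segmentation = unclass(cfg$segmentation),
    chromatin = unclass(cfg$chromatin),
    costes = if (!is.null(cfg$costes)) unclass(cfg$costes)
  )
  out <- structure(
    list(
      nuclei = nuclei, profiles = profiles, coloc = coloc,
      comparisons = comparisons, summary = summary
    ),
    class = "nucoloc_run"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(nuclei, file.path(cfg$out_dir, "nuclei.csv"))
    write_results(profiles, file.path(cfg$out_dir, "profiles.csv"))
    write_results(coloc, file.path(cfg$out_dir, "coloc.csv"))
    if (!is.null(comparisons)) {
      write_results(comparisons, file.path(cfg$out_dir, "comparisons.csv"))
    }
    jsonlite::write_json(
      summary, file.path(cfg$out_dir, "run_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, null = "null"
    )
  }
  out
}

# between-group comparisons over every standard measure
compare_all <- function(nuclei, profiles, coloc, ref, seed) {
  rows <- list()
  add <- function(df, col, name) {
    if (!col %in% names(df)) return()
    cmp <- tryCatch(
      compare_groups(df, !!rlang::sym(col), genotype,
        ref = ref, seed = seed
      ),
      error = function(e) NULL
    )
    if (!is.null(cmp)) {
      g <- glance(cmp)
      g$measure <- name
      rows[[length(rows) + 1L]] <<- g
    }
  }
  add(nuclei, "volume", "volume")
  for (col in grep("^mean_", names(nuclei), value = TRUE)) {
    add(nuclei, col, col)
  }
  pooled <- dplyr::filter(profiles, .data$vector_kind == "pooled")
  for (role in unique(pooled$channel_role)) {
    sub <- dplyr::filter(pooled, .data$channel_role == role)
    sub <- dplyr::mutate(
      sub,
      pc_diff = .data$peripheral_mean - .data$central_mean
    )
    add(sub, "pc_diff", paste0("peripheral_minus_central_", role))
  }
  for (p in unique(coloc$pairing)) {
    sub <- dplyr::filter(coloc, .data$pairing == p)
    for (col in c("m1", "m2", "rho", "tau")) {
      add(sub, col, paste0(p, "_", col))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.nucoloc_run <- function(x, ...) {
  cat("<nucoloc_run>\n")
  cat(sprintf(
    "  nuclei     : %d (%s)\n", nrow(x$nuclei),
    paste(sprintf(
      "%s=%d", names(table(x$nuclei$genotype)), table(x$nuclei$genotype)
    ), collapse = ", ")
  ))
  cat(sprintf(
    "  pairings   : %s\n", paste(unique(x$coloc$pairing), collapse = ", ")
  ))
  if (!is.null(x$comparisons)) {
    sig <- sum(x$comparisons$significant, na.rm = TRUE)
    cat(sprintf(
      "  comparisons: %d measures, %d significant at alpha=%.2g\n",
      nrow(x$comparisons), sig, x$comparisons$alpha[1]
    ))
  }
  invisible(x)
}
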