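#' Load a field-trial dataset from plain-text files
#'
#' Reads the tables written by [write_simulation()] (or equivalently
#' structured real data): counts TSV (genes x samples), sample metadata CSV
#' (sample_id, plant_id, batch, row, col), layout CSV, phenotype CSV and
#' optionally growth-series and temperature CSVs. Counts are
#' integer-checked; plant ids are cross-referenced between metadata,
#' phenotypes and layout, and phenotype-table plants absent from the layout
#' are excluded from spatial stages with a warning.
#'
#' @param dir Directory holding the files.
#' @return List: `counts`, `meta`, `layout`, `phenotypes`, and (when
#'   present) `growth`, `temperature`.
#' @export
read_field_trial <- function(dir) {
  f <- function(x) file.path(dir, x)
  counts <- as.matrix(utils::read.delim(f("counts.tsv"), row.names = 1,
                                        check.names = FALSE))
  if (any(counts != round(counts)) || any(counts < 0))
    stop("non-integer or negative count cell in counts.tsv")
  storage.mode(counts) <- "integer"
  meta <- utils::read.csv(f("samples.csv"), stringsAsFactors = FALSE)
  need <- c("sample_id", "plant_id", "batch", "row", "col")
  if (!all(need %in% colnames(meta)))
    stop("samples.csv must have columns: ", paste(need, collapse = ", "))
  if (!identical(colnames(counts), meta$sample_id))
    stop("counts.tsv columns do not match samples.csv sample_id order")
  layout <- utils::read.csv(f("layout.csv"), stringsAsFactors = FALSE)
  phenotypes <- utils::read.csv(f("phenotypes.csv"), stringsAsFactors = FALSE)
  extra_ph <- setdiff(phenotypes$plant_id, layout$plant_id)
  if (length(extra_ph) > 0)
    warning("phenotype plant(s) absent from layout, excluded from spatial ",
            "stages: ", paste(extra_ph, collapse = ", "))
  out <- list(counts = counts, meta = meta, layout = layout,
              phenotypes = phenotypes)
  if (file.exists(f("growth.csv")))
    out$growth <- utils::read.csv(f("growth.csv"), stringsAsFactors = FALSE)
  if (file.exists(f("temperature.csv")))
    out$temperature <- utils::read.csv(f("temperature.csv"),
                                       stringsAsFactors = FALSE)
  out
}

# rebuild a field_design object from a layout table
.design_from_layout <- function(layout, spacing = NULL) {
  spacing <- spacing %||% {
    xs <- sort(unique(layout$x))
    if (length(xs) > 1) min(diff(xs)) else 0.5
  }
  structure(list(n_rows = max(layout$row) + 1L,
                 n_cols = max(layout$col) + 1L,
                 spacing = spacing, positions = layout),
            class = "field_design")
}

#' Run the single-plant analysis pipeline on one dataset
#'
#' Orchestrates normalization -> variability -> spatial autocorrelation ->
#' single-feature association (-> prediction) on a loaded dataset, with
#' stage toggles. Intended for synthetic or modestly sized real data; each
#' stage is also exposed individually.
#'
#' @param data A dataset as returned by [read_field_trial()] or
#'   [simulate_field_trial()] (with `design` either a `field_design` or
#'   reconstructed from `layout`).
#' @param phenotype Name of the phenotype column to associate/predict
#'   (default `"yield"`).
#' @param stages Character subset of
#'   `c("normalize", "variability", "moran", "assoc", "predict")`.
#' @param n_perm Permutations for the Moran screen.
#' @param selectors,models Selector and learner labels for the prediction
#'   stage.
#' @param seed Integer seed.
#' @return List with one element per executed stage: `rlog` (fit),
#'   `rlog_mat`, `norm_counts`, `variability`, `moran_genes`,
#'   `moran_phenotypes`, `assoc`, `prediction` (list by selector/model),
#'   plus `seed`.
#' @export
run_field_pipeline <- function(data, phenotype = "yield",
                               stages = c("normalize", "variability",
                                          "moran", "assoc"),
                               n_perm = 999L, selectors = "median",
                               models = "enet", seed = 1L) {
  design <- if (inherits(data$design, "field_design")) data$design
    else .design_from_layout(data$layout)
  out <- list(seed = seed)
  counts <- data$counts[rowSums(data$counts) > 0, , drop = FALSE]

  fit <- rlog_fit(counts, data$meta)
  out$rlog <- fit
  out$rlog_mat <- rlog_matrix(fit)
  out$norm_counts <- batch_normalized_counts(counts, fit)
  if (!("normalize" %in% stages)) out[c("rlog", "rlog_mat")] <- NULL

  ph <- data$phenotypes
  plants <- colnames(out$norm_counts)
  ph <- ph[match(plants, ph$plant_id), , drop = FALSE]

  if ("variability" %in% stages)
    out$variability <- variability_report(
      out$norm_counts, ph[, setdiff(colnames(ph), "plant_id"), drop = FALSE])

  if ("moran" %in% stages) {
    out$moran_genes <- moran_screen(out$rlog_mat %||% rlog_matrix(fit),
                                    design, n_perm = n_perm, seed = seed)
    num <- vapply(ph, is.numeric, logical(1))
    Yp <- t(as.matrix(ph[, num, drop = FALSE]))
    colnames(Yp) <- plants
    out$moran_phenotypes <- moran_screen(Yp, design, n_perm = n_perm,
                                         seed = seed + 1L)
  }

  coords <- analysis_coords(design)[plants, , drop = FALSE]
  if ("assoc" %in% stages) {
    rl <- out$rlog_mat %||% rlog_matrix(fit)
    out$assoc <- screen_features(ph[[phenotype]], t(rl), coords)
  }

  if ("predict" %in% stages) {
    rl <- out$rlog_mat %||% rlog_matrix(fit)
    out$prediction <- list()
    for (s in selectors) for (m in models) {
      out$prediction[[paste(s, m, sep = "_")]] <-
        run_repeated_cv(t(rl), ph[[phenotype]], selector = s, model = m,
                        seed = seed)
    }
  }
  out
}
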