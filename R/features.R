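#' Encode age in years into the five-bracket code
#'
#' Brackets: up to 40 -> 0, 41-50 -> 1, 51-60 -> 2, 61-70 -> 3, 71 and
#' above -> 4.  Boundary ages 40/50/60/70 fall in the lower bracket
#' (inclusive upper bound).
#'
#' @param age_years nonnegative integer vector.
#' @return integer codes in `0:4`.
#' @examples
#' encode_age(c(35, 63, 71))
#' @export
encode_age <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0))
    abort("age must be nonnegative")
  as.integer(cut(age_years, breaks = c(-1, 40, 50, 60, 70, Inf),
                 labels = FALSE)) - 1L
}

#' Binding free energy from thermodynamic-cycle terms
#'
#' `dG = dG_bind_vacuum + dG_solv_complex - (dG_solv_ligand +
#' dG_solv_receptor)`, all in kcal/mol.
#'
#' @param terms a list / one-row tibble with `dg_bind_vacuum`,
#'   `dg_solv_complex`, `dg_solv_ligand`, `dg_solv_receptor` (vectors
#'   allowed).
#' @return binding free energy, kcal/mol.
#' @examples
#' binding_free_energy(list(dg_bind_vacuum = -50, dg_solv_complex = -100,
#'                          dg_solv_ligand = -10, dg_solv_receptor = -95))
#' @export
binding_free_energy <- function(terms) {
  req <- c("dg_bind_vacuum", "dg_solv_complex", "dg_solv_ligand",
           "dg_solv_receptor")
  for (r in req)
    if (is.null(terms[[r]]) || anyNA(terms[[r]]))
      abort(paste0("missing energy term: ", r))
  terms$dg_bind_vacuum + terms$dg_solv_complex -
    (terms$dg_solv_ligand + terms$dg_solv_receptor)
}

#' Feature-group column names
#'
#' The model-ready table carries three feature groups: demographic and
#' clinical information (DCI), MM-GBSA energy components, and the
#' trajectory-derived geometric descriptors.  Response is strictly the
#' prediction target and survival time is metadata; neither is ever a
#' model input.
#'
#' @param composites include the composite columns in each group.
#' @return named list of character vectors (`dci`, `energy`, `geometric`).
#' @export
feature_groups <- function(composites = FALSE) {
  g <- list(
    dci = c("age_code", "sex_code", "smoking_code"),
    energy = c("vdw", "eel", "esurf", "epb"),
    geometric = c("matching_rate", "convex_atoms", "connectivity",
                  "euclidean_distance", "hydrogen_bonds")
  )
  if (composites) {
    g$dci <- c(g$dci, "x_p")
    g$energy <- c(g$energy, "x_e1")
    g$geometric <- c(g$geometric, "x_g1", "x_g2")
  }
  g
}

#' Assemble the model-ready feature table
#'
#' Joins the clinical, energy and geometric tables on `patient_id`, encodes
#' age, and returns one row per patient with the raw feature columns, the
#' response label, and survival carried as metadata.  Rows with a patient
#' missing from any input table are dropped with a warning.
#'
#' @param clinical tibble from [read_clinical_table()].
#' @param energy tibble from [read_energy_table()].
#' @param geometric tibble with `patient_id` plus the geometric feature
#'   columns of [extract_geometric_features()].
#' @return feature tibble (one row per patient).
#' @export
assemble_features <- function(clinical, energy, geometric) {
  ids <- Reduce(intersect, list(clinical$patient_id, energy$patient_id,
                                geometric$patient_id))
  dropped <- setdiff(unique(c(clinical$patient_id, energy$patient_id,
                              geometric$patient_id)), ids)
  if (length(dropped) > 0)
    warn(paste0("dropping ", length(dropped),
                " patient(s) missing from some input table"))
  gg <- feature_groups()
  out <- clinical %>%
    filter(.data$patient_id %in% ids) %>%
    mutate(age_code = encode_age(.data$age_years)) %>%
    select("patient_id", "age_code", "sex_code", "smoking_code",
           "survival_months", "response_label") %>%
    left_join(select(energy, "patient_id", dplyr::all_of(gg$energy)),
              by = "patient_id") %>%
    left_join(select(geometric, "patient_id", dplyr::all_of(gg$geometric)),
              by = "patient_id")
  out
}

#' Fit a z-score normalizer on training rows
#'
#' Per-feature mean and population standard deviation (`z = (x - mu) /
#' sigma`), fitted on the supplied rows only so test rows can be
#' transformed without leakage.  Constant features (`sigma = 0`) transform
#' to 0 and are flagged.
#'
#' @param rows feature tibble (training rows).
#' @param columns columns to normalize; default all feature-group columns
#'   present.
#' @param method `"zscore"` (default) or `"minmax"` (maps the training
#'   range to `[0, 1]`, never clipping test rows).
#' @return object of class `bindresp_normalizer`.
#' @export
fit_normalizer <- function(rows, columns = NULL,
                           method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (nrow(rows) < 2) abort("need at least 2 rows to fit a normalizer")
  if (is.null(columns))
    columns <- intersect(unlist(feature_groups()), names(rows))
  if (length(columns) == 0) abort("no feature columns to normalize")
  mu <- vapply(columns, function(cl) mean(rows[[cl]]), numeric(1))
  sigma <- vapply(columns, function(cl) {
    v <- rows[[cl]]
    if (method == "zscore") sqrt(mean((v - mean(v))^2)) else diff(range(v))
  }, numeric(1))
  if (method == "minmax")
    mu <- vapply(columns, function(cl) min(rows[[cl]]), numeric(1))
  structure(list(columns = columns, mu = mu, sigma = sigma,
                 constant = sigma == 0, method = method,
                 n_train = nrow(rows)),
            class = "bindresp_normalizer")
}

#' Apply a fitted normalizer
#'
#' Transforms the normalizer's columns with the training statistics.
#' Applying a normalizer to already-normalized rows is refused.
#'
#' @param model a `bindresp_normalizer`.
#' @param rows feature tibble.
#' @return `rows` with normalized feature columns and attribute
#'   `normalized = TRUE`.
#' @export
apply_normalizer <- function(model, rows) {
  stopifnot(inherits(model, "bindresp_normalizer"))
  if (isTRUE(attr(rows, "normalized")))
    abort("rows are already normalized; refusing to normalize twice")
  for (i in seq_along(model$columns)) {
    cl <- model$columns[i]
    if (!cl %in% names(rows)) abort(paste0("missing column: ", cl))
    rows[[cl]] <- if (model$constant[i]) 0
                  else (rows[[cl]] - model$mu[i]) / model$sigma[i]
  }
  attr(rows, "normalized") <- TRUE
  attr(rows, "normalizer") <- model
  rows
}

#' @export
tidy.bindresp_normalizer <- function(x, ...) {
  tibble(column = x$columns, mu = unname(x$mu), sigma = unname(x$sigma),
         constant = unname(x$constant), method = x$method)
}

#' Build composite features
#'
#' Each composite is the mean of its z-scored constituents: `x_g1` from
#' (matching_rate, connectivity, hydrogen_bonds), `x_g2` from
#' (convex_atoms, euclidean_distance), `x_p` from the DCI codes and `x_e1`
#' from the energy components.  The aggregation operator (mean of z-scored
#' constituents) is scale-free and order-independent; constituents are
#' retained so models may use either representation.
#'
#' @param rows feature tibble with raw constituent columns.
#' @param normalizer optional pre-fitted [fit_normalizer()] model (fit it
#'   on training rows to avoid leakage); default fits on `rows`.
#' @return `rows` with `x_g1`, `x_g2`, `x_p`, `x_e1` appended.
#' @export
build_composites <- function(rows, normalizer = NULL) {
  parts <- list(
    x_g1 = c("matching_rate", "connectivity", "hydrogen_bonds"),
    x_g2 = c("convex_atoms", "euclidean_distance"),
    x_p = c("age_code", "sex_code", "smoking_code"),
    x_e1 = c("vdw", "eel", "esurf", "epb")
  )
  need <- unlist(parts)
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0)
    abort(paste0("missing composite constituent(s): ",
                 paste(missing, collapse = ", ")))
  if (is.null(normalizer)) normalizer <- fit_normalizer(rows, columns = need)
  z <- apply_normalizer(normalizer, rows[need])
  for (nm in names(parts))
    rows[[nm]] <- rowMeans(as.data.frame(z[parts[[nm]]]))
  rows
}
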