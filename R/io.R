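# Tidy plate-table CSV dialects, reporting, and the paired comparison
# used for between-curve statistics.
#
# Fixed column headers per assay type (no standard format exists for
# plate pharmacology, so the dialect is exact by design):
#   dose_response: ligand,receptor,conc_M,response,replicate
#   competition:   radioligand,competitor,receptor,tracer_conc_nM,
#                  competitor_conc_M,bound_cpm,replicate
#   kinetics:      phase,time_min,total_cpm,nonspecific_cpm,
#                  tracer_conc_nM,replicate
#   bret:          ligand,receptor,conc_M,acceptor,donor,replicate

.dialects <- list(
  dose_response = list(
    cols = c("ligand", "receptor", "conc_M", "response", "replicate"),
    num = c("conc_M", "response", "replicate")),
  competition = list(
    cols = c("radioligand", "competitor", "receptor", "tracer_conc_nM",
             "competitor_conc_M", "bound_cpm", "replicate"),
    num = c("tracer_conc_nM", "competitor_conc_M", "bound_cpm",
            "replicate")),
  kinetics = list(
    cols = c("phase", "time_min", "total_cpm", "nonspecific_cpm",
             "tracer_conc_nM", "replicate"),
    num = c("time_min", "total_cpm", "nonspecific_cpm", "tracer_conc_nM",
            "replicate")),
  bret = list(
    cols = c("ligand", "receptor", "conc_M", "acceptor", "donor",
             "replicate"),
    num = c("conc_M", "acceptor", "donor", "replicate"))
)

#' Read a tidy assay CSV
#'
#' Reads one of the fixed CSV dialects (see the package vignette),
#' validates the header, coerces numeric columns, and rejects malformed
#' rows (non-numeric or negative where counts/concentrations are
#' required) with a warning that lists the offending file line numbers.
#'
#' @param path path to the CSV file
#' @param assay_type one of "dose_response", "competition", "kinetics",
#'   "bret"
#' @return a validated data.frame with attribute \code{assay_type};
#'   convert to the analysis containers with [asDoseResponseCurve()],
#'   [asCompetitionCurve()] or [asKineticTrace()]
#' @export
readAssayCsv <- function(path, assay_type = names(.dialects)) {
  assay_type <- match.arg(assay_type)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- .dialects[[assay_type]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spec$cols, names(df))
  if (length(missing))
    stop("missing required column(s) for ", assay_type, ": ",
         paste(missing, collapse = ", "))
  df <- df[spec$cols]
  if (nrow(df) == 0) stop("empty table: ", path)
  for (cn in spec$num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  bad <- rowSums(is.na(df[spec$num])) > 0
  conc_cols <- intersect(c("conc_M", "competitor_conc_M", "tracer_conc_nM",
                           "time_min"), spec$num)
  for (cn in conc_cols) bad <- bad | (!is.na(df[[cn]]) & df[[cn]] < 0)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) rejected at file line(s) ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid rows left in ", path)
  attr(df, "assay_type") <- assay_type
  df
}

#' Write an assay container to its CSV dialect
#'
#' The competition dialect carries the nonspecific channel as separate
#' rows with receptor label "mock" (mirroring a mock-transfected control
#' plate); the other dialects map one well per row.
#'
#' @param object a DoseResponseCurve, CompetitionCurve, KineticTrace or
#'   the data.frame returned by [simulateBret()]
#' @param path output CSV path
#' @param ligand_id,receptor_id labels used when the object carries none
#' @return the path, invisibly
#' @export
writeAssayCsv <- function(object, path, ligand_id = "ligand",
                          receptor_id = "receptor") {
  orEmpty <- function(x, alt) if (is.na(x)) alt else x
  if (is(object, "DoseResponseCurve")) {
    df <- data.frame(ligand = orEmpty(object@ligand_id, ligand_id),
                     receptor = orEmpty(object@receptor_id, receptor_id),
                     conc_M = object@conc, response = object@response,
                     replicate = object@replicate)
  } else if (is(object, "CompetitionCurve")) {
    main <- data.frame(
      radioligand = orEmpty(object@radioligand_id, ligand_id),
      competitor = orEmpty(object@competitor_id, ligand_id),
      receptor = orEmpty(object@receptor_id, receptor_id),
      tracer_conc_nM = object@tracer_conc_L,
      competitor_conc_M = object@competitor_conc,
      bound_cpm = object@bound, replicate = object@replicate)
    mock <- main
    mock$receptor <- "mock"
    mock$bound_cpm <- object@nonspecific
    df <- rbind(main, mock)
  } else if (is(object, "KineticTrace")) {
    df <- data.frame(phase = object@phase, time_min = object@time,
                     total_cpm = object@total,
                     nonspecific_cpm = object@nonspecific,
                     tracer_conc_nM = object@tracer_conc_L,
                     replicate = object@replicate)
  } else if (is.data.frame(object) &&
             all(c("conc_M", "acceptor", "donor") %in% names(object))) {
    df <- data.frame(ligand = ligand_id, receptor = receptor_id,
                     conc_M = object$conc_M, acceptor = object$acceptor,
                     donor = object$donor, replicate = object$replicate)
  } else stop("unsupported object for writeAssayCsv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert validated assay tables to analysis containers
#'
#' @param df a data.frame from [readAssayCsv()]
#' @return the matching S4 container
#' @export
asDoseResponseCurve <- function(df) {
  key <- unique(df[c("ligand", "receptor")])
  if (nrow(key) > 1)
    stop("table contains multiple ligand/receptor pairings; subset first")
  DoseResponseCurve(conc = df$conc_M, response = df$response,
                    replicate = df$replicate, ligand_id = key$ligand,
                    receptor_id = key$receptor)
}

#' @rdname asDoseResponseCurve
#' @param mock_receptor receptor label of the nonspecific channel rows
#' @export
asCompetitionCurve <- function(df, mock_receptor = "mock") {
  is_mock <- df$receptor == mock_receptor
  main <- df[!is_mock, , drop = FALSE]
  mock <- df[is_mock, , drop = FALSE]
  if (nrow(main) == 0) stop("no receptor rows in competition table")
  ns <- if (nrow(mock)) {
    idx <- match(interaction(main$competitor_conc_M, main$replicate),
                 interaction(mock$competitor_conc_M, mock$replicate))
    if (any(is.na(idx)))
      stop("mock (nonspecific) rows do not match receptor wells")
    mock$bound_cpm[idx]
  } else 0
  CompetitionCurve(competitor_conc = main$competitor_conc_M,
                   bound = main$bound_cpm, nonspecific = ns,
                   tracer_conc_L = unique(main$tracer_conc_nM)[1],
                   replicate = main$replicate,
                   radioligand_id = main$radioligand[1],
                   competitor_id = main$competitor[1],
                   receptor_id = main$receptor[1])
}

#' @rdname asDoseResponseCurve
#' @export
asKineticTrace <- function(df) {
  phase <- unique(df$phase)
  if (length(phase) > 1)
    stop("table contains multiple phases; subset first")
  KineticTrace(time = df$time_min, total = df$total_cpm,
               nonspecific = df$nonspecific_cpm,
               tracer_conc_L = unique(df$tracer_conc_nM)[1],
               phase = phase, replicate = df$replicate)
}

#' Paired Student's t-test on matched per-experiment summaries
#'
#' Classical two-sided paired t-test on the differences of matched
#' per-experiment values (e.g. pEC50s of the same ligand pair measured in
#' the same experiments). Zero-variance nonzero differences are degenerate
#' (infinite t); they are reported as p = 0 with a warning rather than an
#' error.
#'
#' @param values_a,values_b matched numeric vectors, length >= 2
#' @return a list with elements \code{t}, \code{df} and \code{p}
#' @examples
#' pairedTTest(c(1, 2, 3), c(3, 5, 4))
#' @export
pairedTTest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("unmatched lengths: paired test needs matched vectors")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 matched pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    warning("zero-variance nonzero differences: degenerate paired t-test",
            call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

.fmtOrLabel <- function(x, label, digits) {
  if (is.na(x)) label else format(signif(x, digits), trim = TRUE)
}

#' Report tables for fitted results
#'
#' Deterministic, rounded summary tables in the layout of a functional
#' characterization table (pEC50, EC50, efficacy, n), a competition-
#' binding table (pIC50, Ki/KD, \% max, n) and a kinetic-constants panel.
#' Non-saturating fits propagate as "N.A." and no-binding results as
#' "N.B." labels rather than numbers.
#'
#' @param fits named list of [LogisticFit-class] objects
#' @param efficacy,n optional vectors matched to \code{fits}
#' @return a data.frame with fixed column order
#' @export
reportFunctional <- function(fits, efficacy = NA, n = NA) {
  efficacy <- rep_len(efficacy, length(fits))
  n <- rep_len(n, length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (f@na_call) {
      data.frame(ligand = f@ligand_id, receptor = f@receptor_id,
                 pEC50 = "N.A.", SEM = "N.A.", EC50_nM = "N.A.",
                 efficacy = "N.A.", n = n[i])
    } else {
      data.frame(ligand = f@ligand_id, receptor = f@receptor_id,
                 pEC50 = format(round(f@pec50, 1), nsmall = 1),
                 SEM = .fmtOrLabel(f@se_pec50, "-", 2),
                 EC50_nM = format(signif(f@ec50_nM, 2), trim = TRUE),
                 efficacy = .fmtOrLabel(efficacy[i], "-", 3), n = n[i])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(fits)
  out
}

#' @rdname reportFunctional
#' @param results named list of [EquilibriumResult-class] objects
#' @param pct_max optional \% of reference specific binding per result
#' @export
reportBinding <- function(results, pct_max = NA, n = NA) {
  pct_max <- rep_len(pct_max, length(results))
  n <- rep_len(n, length(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (r@nb) {
      data.frame(pIC50 = "N.B.", SEM = "N.B.", constant_nM = "N.B.",
                 constant = "N.B.", pct_max = "N.B.", n = n[i])
    } else {
      const <- if (r@mode == "homologous") r@kd_nM else r@ki_nM
      data.frame(pIC50 = format(round(r@pic50, 1), nsmall = 1),
                 SEM = .fmtOrLabel(r@se_pic50, "-", 2),
                 constant_nM = format(signif(const, 2), trim = TRUE),
                 constant = if (r@mode == "homologous") "KD" else "Ki",
                 pct_max = .fmtOrLabel(pct_max[i], "-", 3), n = n[i])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(results)
  out
}

#' @rdname reportFunctional
#' @param constants named list of [KineticConstants-class] objects
#' @export
reportKinetics <- function(constants) {
  rows <- lapply(constants, function(k) {
    data.frame(
      kobs_per_min = signif(k@kobs, 3), se_kobs = signif(k@se_kobs, 2),
      koff_per_min = signif(k@koff, 3), se_koff = signif(k@se_koff, 2),
      kon_per_nM_per_min = signif(k@kon, 3), se_kon = signif(k@se_kon, 2),
      KD_nM = signif(k@kd_nM, 3), se_KD = signif(k@se_kd, 2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(constants)
  out
}

#' Serialize fitted results to JSON with unit-explicit keys
#'
#' @param object a LogisticFit, EquilibriumResult, KineticConstants,
#'   SchildFit, or a (possibly nested) named list of them
#' @param path output JSON path
#' @return the path, invisibly
#' @export
writeResultsJson <- function(object, path) {
  jsonlite::write_json(.toResultList(object), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.toResultList <- function(object) {
  if (is(object, "LogisticFit")) {
    if (object@na_call) return(list(call = "N.A."))
    list(pec50 = object@pec50, se_pec50 = object@se_pec50,
         ec50_nM = object@ec50_nM, basal = object@basal,
         span = object@emax, hill = object@hill,
         converged = object@converged, n_points = object@n_points)
  } else if (is(object, "EquilibriumResult")) {
    if (object@nb) return(list(call = "N.B."))
    list(pic50 = object@pic50, se_pic50 = object@se_pic50,
         ic50_nM = object@ic50_nM, b0_cpm = object@b0_cpm,
         bmax_cpm = object@bmax_cpm, kd_nM = object@kd_nM,
         ki_nM = object@ki_nM, mode = object@mode)
  } else if (is(object, "KineticConstants")) {
    list(kobs_per_min = object@kobs, se_kobs = object@se_kobs,
         koff_per_min = object@koff, se_koff = object@se_koff,
         kon_per_nM_per_min = object@kon, se_kon = object@se_kon,
         kd_nM = object@kd_nM, se_kd = object@se_kd,
         tracer_conc_nM = object@tracer_conc_L)
  } else if (is(object, "SchildFit")) {
    list(slope = object@slope, se_slope = object@se_slope,
         pa2 = object@pa2, a2_nM = object@a2_nM, r2 = object@r2,
         n_points = object@n_points, n_excluded = object@n_excluded)
  } else if (is.list(object)) {
    lapply(object, .toResultList)
  } else object
}
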