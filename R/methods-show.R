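.fmt <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", format(signif(x, digits), trim = TRUE))
}

setMethod("show", "SystemParams", function(object) {
  cat("SystemParams: Bmax", .fmt(object@bmax_cpm), "CPM, KD",
      .fmt(object@kd_nM), "nM\n")
  if (!is.na(object@kon))
    cat("  kon", .fmt(object@kon), "nM^-1 min^-1, koff",
        .fmt(object@koff), "min^-1\n")
  cat("  nonspecific fraction", .fmt(object@ns_fraction), ", noise CV",
      .fmt(object@noise_cv), ", seed",
      ifelse(is.na(object@seed), "unset", object@seed), "\n")
})

setMethod("show", "FunctionalParams", function(object) {
  cat("FunctionalParams: EC50", .fmt(object@ec50_nM), "nM, Emax fraction",
      .fmt(object@emax_frac), ", basal", .fmt(object@basal), "\n")
  if (!is.na(object@kb_nM)) cat("  antagonist KB", .fmt(object@kb_nM), "nM\n")
})

setMethod("show", "DoseResponseCurve", function(object) {
  cat("DoseResponseCurve:", object@ligand_id, "at", object@receptor_id,
      "\n ", length(object@conc), "wells,",
      length(unique(object@conc[object@conc > 0])),
      "positive concentrations,", length(unique(object@replicate)),
      "replicate(s)\n")
})

setMethod("show", "LogisticFit", function(object) {
  kind <- if (object@hill > 0) "activation" else "inhibition"
  if (object@na_call) {
    cat("LogisticFit (", kind, "): N.A. (non-saturating)\n", sep = "")
  } else {
    cat("LogisticFit (", kind, "): p",
        if (object@hill > 0) "EC50 " else "IC50 ",
        .fmt(object@pec50, 4), " +/- ", .fmt(object@se_pec50, 2),
        " (", .fmt(object@ec50_nM), " nM)\n", sep = "")
    cat("  basal", .fmt(object@basal), ", span", .fmt(object@emax),
        ", n =", object@n_points,
        if (!object@converged) ", NOT converged" else "", "\n")
  }
})

setMethod("show", "CompetitionCurve", function(object) {
  cat("CompetitionCurve:", object@radioligand_id, "displaced by",
      object@competitor_id, "at", object@receptor_id, "\n  tracer",
      .fmt(object@tracer_conc_L), "nM,", length(object@bound), "wells\n")
})

setMethod("show", "EquilibriumResult", function(object) {
  if (object@nb) {
    cat("EquilibriumResult (", object@mode, "): N.B. (no binding)\n",
        sep = "")
  } else {
    cat("EquilibriumResult (", object@mode, "): pIC50 ",
        .fmt(object@pic50, 4), " (IC50 ", .fmt(object@ic50_nM), " nM)\n",
        sep = "")
    if (!is.na(object@kd_nM))
      cat("  KD", .fmt(object@kd_nM), "nM, Bmax", .fmt(object@bmax_cpm),
          "CPM\n")
    if (!is.na(object@ki_nM)) cat("  Ki", .fmt(object@ki_nM), "nM\n")
  }
})

setMethod("show", "KineticTrace", function(object) {
  cat("KineticTrace (", object@phase, "): tracer ",
      .fmt(object@tracer_conc_L), " nM, ",
      length(unique(object@replicate)), " replicate(s), ",
      length(unique(object@time)), " time points\n", sep = "")
})

setMethod("show", "KineticFit", function(object) {
  lab <- if (object@phase == "association") "kobs" else "koff"
  cat("KineticFit (", object@phase, "): ", lab, " = ",
      .fmt(object@rate, 4), " +/- ", .fmt(object@se_rate, 2),
      " min^-1, amplitude ", .fmt(object@amplitude), " CPM\n", sep = "")
})

setMethod("show", "KineticConstants", function(object) {
  cat("KineticConstants (L =", .fmt(object@tracer_conc_L), "nM):\n")
  cat("  kobs", .fmt(object@kobs, 4), "+/-", .fmt(object@se_kobs, 2),
      "min^-1\n")
  cat("  koff", .fmt(object@koff, 4), "+/-", .fmt(object@se_koff, 2),
      "min^-1\n")
  cat("  kon ", .fmt(object@kon, 4), "+/-", .fmt(object@se_kon, 2),
      "nM^-1 min^-1\n")
  cat("  KD  ", .fmt(object@kd_nM, 4), "+/-", .fmt(object@se_kd, 2),
      "nM\n")
})

setMethod("show", "SchildFit", function(object) {
  cat("SchildFit: slope", .fmt(object@slope, 3), "+/-",
      .fmt(object@se_slope, 2), ", pA2", .fmt(object@pa2, 4), "(A2",
      .fmt(object@a2_nM), "nM), n =", object@n_points, "\n")
})

#' Coerce assay containers to data frames
#'
#' @param x a DoseResponseCurve, CompetitionCurve or KineticTrace
#' @param row.names,optional,... passed through for S3 compatibility
#' @return a tidy long-format data.frame, one row per well/time point
#' @export
as.data.frame.DoseResponseCurve <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(ligand = x@ligand_id, receptor = x@receptor_id,
             conc_M = x@conc, response = x@response,
             replicate = x@replicate)
}

#' @rdname as.data.frame.DoseResponseCurve
#' @export
as.data.frame.CompetitionCurve <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(radioligand = x@radioligand_id, competitor = x@competitor_id,
             receptor = x@receptor_id, tracer_conc_nM = x@tracer_conc_L,
             competitor_conc_M = x@competitor_conc, bound_cpm = x@bound,
             nonspecific_cpm = x@nonspecific, replicate = x@replicate)
}

#' @rdname as.data.frame.DoseResponseCurve
#' @export
as.data.frame.KineticTrace <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(phase = x@phase, time_min = x@time, total_cpm = x@total,
             nonspecific_cpm = x@nonspecific, specific_cpm = x@specific,
             tracer_conc_nM = x@tracer_conc_L, replicate = x@replicate)
}

setMethod("as.data.frame", "DoseResponseCurve", as.data.frame.DoseResponseCurve)
setMethod("as.data.frame", "CompetitionCurve", as.data.frame.CompetitionCurve)
setMethod("as.data.frame", "KineticTrace", as.data.frame.KineticTrace)
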