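# Monoisotopic masses of the most abundant isotope (Da), IUPAC/CODATA.
# Carbon is exactly 12 by definition of the atomic mass scale.
.element_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740,
  O  = 15.9949146,
  Na = 22.9897693,
  K  = 38.9637065,
  S  = 31.9720707,
  P  = 30.9737615,
  F  = 18.9984032,
  Cl = 34.9688527,
  Br = 78.9183376,
  I  = 126.9044719
)

.electron_mass <- 0.000549

.halogens <- c("F", "Cl", "Br", "I")

# Built-in adduct table: neutral-mass delta (Da) and signed charge.
.builtin_adducts <- list(
  "[M+H]+"   = list(delta = 1.0078250319, charge = 1L),
  "[M+Na]+"  = list(delta = 22.9897693, charge = 1L),
  "[M+K]+"   = list(delta = 38.9637065, charge = 1L),
  "[M+NH4]+" = list(delta = 14.0030740 + 4 * 1.0078250319, charge = 1L),
  "[M+2H]2+" = list(delta = 2 * 1.0078250319, charge = 2L),
  "[M-H]-"   = list(delta = -1.0078250319, charge = -1L)
)

#' Parse a molecular formula
#'
#' Hill-style element-count strings such as `"C27H40N2O4"`. An omitted
#' count means 1. Unknown element symbols are rejected.
#'
#' @param text formula string.
#' @return Named integer vector of element counts, class `mol_formula`.
#' @export
parse_formula <- function(text) {
  if (inherits(text, "mol_formula")) return(text)
  if (!is.character(text) || length(text) != 1 || !nzchar(text))
    stop_validation("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(toks) == 0)
    stop_data(sprintf("malformed formula '%s'", text))
  counts <- integer(0)
  for (tok in toks) {
    sym <- gsub("[0-9]", "", tok)
    cnt <- gsub("[A-Za-z]", "", tok)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(.element_masses))
      stop_data(sprintf("unknown element '%s' in formula '%s'", sym, text))
    if (cnt < 1)
      stop_data(sprintf("element count must be positive in '%s'", text))
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
  }
  structure(counts, class = "mol_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum of the atomic masses of the most abundant isotopes.
#'
#' @param f a `mol_formula` or formula string.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  sum(.element_masses[names(f)] * as.integer(f))
}

#' Theoretical m/z of an adduct ion
#'
#' `m/z = (M + delta - z * m_e) / |z|` where `M` is the neutral
#' monoisotopic mass, `delta` and signed charge `z` come from the adduct
#' specifier, and `m_e = 0.000549` Da is the electron mass. The electron
#' correction is an explicit flag: high-resolution work calibrated on
#' ion masses uses it, whereas summing the atomic masses of the ion
#' formula (e.g. treating a protonated acid as its own neutral-atom
#' formula) amounts to leaving it off.
#'
#' @param x a `mol_formula`, a formula string, or a neutral monoisotopic
#'   mass in Da.
#' @param adduct name of a built-in adduct (`"[M+H]+"`, `"[M+Na]+"`,
#'   `"[M+K]+"`, `"[M+NH4]+"`, `"[M+2H]2+"`, `"[M-H]-"`) or a
#'   `list(delta = , charge = )` with a mass delta in Da and a signed
#'   non-zero integer charge.
#' @param electron_correction subtract `z * m_e` (default `TRUE`).
#' @return m/z in Thomson.
#' @export
adduct_mz <- function(x, adduct, electron_correction = TRUE) {
  M <- if (is.numeric(x) && !inherits(x, "mol_formula")) x
       else monoisotopic_mass(x)
  if (is.character(adduct)) {
    if (!adduct %in% names(.builtin_adducts))
      stop_usage(sprintf("unknown adduct '%s'", adduct))
    adduct <- .builtin_adducts[[adduct]]
  }
  z <- as.integer(adduct$charge)
  if (z == 0L) stop_validation("adduct charge must be non-zero")
  mz <- M + adduct$delta
  if (electron_correction) mz <- mz - z * .electron_mass
  mz / abs(z)
}

#' Ring and double bond equivalents (degrees of unsaturation)
#'
#' `RDBE = C + 1 + (N - H - X) / 2` with halogens `X` counted like
#' hydrogen; oxygen and sulfur do not enter. Computed for the standalone
#' neutral formula (no substructure bookkeeping).
#'
#' @param f a `mol_formula` or formula string.
#' @return RDBE as a numeric scalar.
#' @export
rdbe <- function(f) {
  f <- parse_formula(f)
  cnt <- function(el) if (el %in% names(f)) as.integer(f[[el]]) else 0L
  hal <- sum(vapply(.halogens, cnt, integer(1)))
  cnt("C") + 1 + (cnt("N") - cnt("H") - hal) / 2
}

#' Read a reference-compound table
#'
#' CSV with header `name,formula,neutral_mass,adducts`; each row must
#' fill exactly one of `formula` and `neutral_mass`, and lists its
#' adducts as semicolon-separated specifiers (empty means the default
#' set supplied at match time).
#'
#' @param path CSV file path.
#' @return Data frame of class `reference_set` with columns `name`,
#'   `formula`, `neutral_mass`, `adducts` (list column).
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("name", "formula", "neutral_mass", "adducts")
  if (!all(need %in% names(df)))
    stop_data(sprintf("'%s' must have columns %s", path,
                      paste(need, collapse = ",")))
  if (anyDuplicated(df$name))
    stop_validation(sprintf("duplicate compound name(s) in '%s'", path))
  has_f <- nzchar(df$formula)
  has_m <- nzchar(df$neutral_mass)
  if (any(has_f == has_m))
    stop_validation(sprintf(
      "row(s) %s of '%s' must fill exactly one of formula/neutral_mass",
      paste(which(has_f == has_m), collapse = ","), path))
  mass <- ifelse(has_m, suppressWarnings(as.numeric(df$neutral_mass)),
                 NA_real_)
  if (any(has_m & (is.na(mass) | mass <= 0)))
    stop_validation(sprintf("invalid neutral_mass in '%s'", path))
  out <- data.frame(name = df$name, formula = ifelse(has_f, df$formula, NA),
                    neutral_mass = mass, stringsAsFactors = FALSE)
  out$adducts <- lapply(df$adducts, function(a)
    if (nzchar(a)) strsplit(a, ";", fixed = TRUE)[[1]] else character(0))
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Dereplicate bucket-table features against reference compounds
#'
#' For every feature and every (compound, adduct) pair, an annotation is
#' emitted when the observed feature m/z lies within `mz_tol` of the
#' theoretical adduct m/z. A feature may carry several annotations;
#' features with none are flagged "not dereplicated" -- in a discovery
#' context these are the interesting ones.
#'
#' @param table a [bucket_table()] (feature m/z taken from its keys).
#' @param refs a `reference_set` from [read_reference_csv()], or a data
#'   frame with columns `name` plus `formula` or `neutral_mass` and an
#'   `adducts` list column.
#' @param mz_tol matching tolerance in Da (> 0; 0 demands exact match).
#' @param default_adducts adducts used for reference rows that list none.
#' @param electron_correction passed to [adduct_mz()].
#' @return List with `annotations` (data frame: `feature_key`,
#'   `compound`, `adduct`, `observed_mz`, `theoretical_mz`, `delta`) and
#'   `not_dereplicated` (character vector of feature keys).
#' @export
match_reference <- function(table, refs, mz_tol,
                            default_adducts = c("[M+H]+", "[M+Na]+"),
                            electron_correction = TRUE) {
  if (mz_tol < 0) stop_validation("mz_tol must be >= 0")
  keys <- colnames(table)
  obs <- attr(table, "feature_mz")
  if (is.null(obs)) obs <- parse_feature_keys(keys)$mz
  ann <- list()
  for (i in seq_len(nrow(refs))) {
    M <- if (!is.na(refs$neutral_mass[i])) refs$neutral_mass[i]
         else monoisotopic_mass(refs$formula[i])
    adds <- refs$adducts[[i]]
    if (length(adds) == 0) adds <- default_adducts
    for (a in adds) {
      theo <- adduct_mz(M, a, electron_correction = electron_correction)
      hit <- which(!is.na(obs) & abs(obs - theo) <= mz_tol)
      if (length(hit))
        ann[[length(ann) + 1L]] <- data.frame(
          feature_key = keys[hit], compound = refs$name[i], adduct = a,
          observed_mz = obs[hit], theoretical_mz = theo,
          delta = obs[hit] - theo)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann)
    else data.frame(feature_key = character(0), compound = character(0),
                    adduct = character(0), observed_mz = numeric(0),
                    theoretical_mz = numeric(0), delta = numeric(0))
  annotations <- annotations[order(annotations$feature_key,
                                   annotations$compound), , drop = FALSE]
  rownames(annotations) <- NULL
  list(annotations = annotations,
       not_dereplicated = setdiff(keys, annotations$feature_key))
}

#' Match observed fragment peaks to candidate fragment masses
#'
#' A candidate matches an observed peak when
#' `|observed - (mass + k * 1.007825)| <= mz_tol` for some integer
#' hydrogen shift `k` with `|k| <= max_h_shifts` -- fragment ions often
#' differ from the formal substructure mass by one or more hydrogen
#' rearrangements. The smallest `|k|` is reported; ties between `+k` and
#' `-k` go to the smaller mass error.
#'
#' @param observed data frame (or 2-column matrix) of observed fragment
#'   `mz` and `intensity`.
#' @param candidates data frame with `label` and `mass` columns.
#' @param mz_tol matching tolerance in Da.
#' @param max_h_shifts maximum number of hydrogen rearrangements allowed
#'   (>= 0).
#' @return Data frame with one row per matched candidate: `label`,
#'   `matched_mz`, `h_shift`, `delta`.
#' @export
match_fragments <- function(observed, candidates, mz_tol,
                            max_h_shifts = 0L) {
  if (max_h_shifts < 0) stop_validation("max_h_shifts must be >= 0")
  h <- .element_masses[["H"]]
  observed <- as.data.frame(observed)
  if (nrow(observed) > 0 && is.null(observed$mz))
    names(observed)[1:2] <- c("mz", "intensity")
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    found <- NULL
    for (ak in 0:max_h_shifts) {
      for (k in unique(c(ak, -ak))) {
        target <- candidates$mass[i] + k * h
        if (nrow(observed) == 0) next
        deltas <- observed$mz - target
        j <- which.min(abs(deltas))
        if (length(j) && abs(deltas[j]) <= mz_tol) {
          cand <- list(mz = observed$mz[j], k = k, delta = deltas[j])
          if (is.null(found) || abs(cand$delta) < abs(found$delta))
            found <- cand
        }
      }
      if (!is.null(found)) break   # smallest |k| wins
    }
    if (!is.null(found))
      out[[length(out) + 1L]] <- data.frame(
        label = candidates$label[i], matched_mz = found$mz,
        h_shift = found$k, delta = found$delta)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(label = character(0), matched_mz = numeric(0),
                  h_shift = integer(0), delta = numeric(0))
}
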