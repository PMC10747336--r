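# Exact-mass, adduct and ppm arithmetic, biotransformation annotation and
# MS2 neutral-loss ladders.
#
# All masses are frozen constants (monoisotopic, Da) rather than looked up
# from an external table at run time, so results are reproducible across
# library versions. Charged-species arithmetic carries the electron mass:
# the proton constant below is m(H) - m(e).

.ATOMIC_MASS <- c(
  C  = 12,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  Cl = 34.96885268
)

.ELECTRON_MASS <- 0.0005486
.PROTON_MASS <- 1.0072765   # H minus one electron
.FORMIC_ACID <- 46.0054793  # CH2O2

#' Parse a molecular formula
#'
#' Parses a Hill-style element-count string (no parentheses, charges or
#' isotope labels) into a named integer vector of element counts. Only the
#' elements C, H, N, O, S and Cl are supported; an element without an
#' explicit count gets count 1.
#'
#' @param text formula string, e.g. `"C22H22O10"` or `"C7H13NO2"`.
#' @return a named integer vector of class `"chem_formula"`.
#' @export
#' @examples
#' parse_formula("C22H22O10")
#' parse_formula("C7H13NO2")  # implicit N1
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!identical(paste0(tokens, collapse = ""), text))
    stop("malformed formula: '", text, "'", call. = FALSE)
  el <- sub("[0-9]*$", "", tokens)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- integer(length(.ATOMIC_MASS))
  names(counts) <- names(.ATOMIC_MASS)
  for (i in seq_along(el)) counts[el[i]] <- counts[el[i]] + n[i]
  if (all(counts == 0L)) stop("empty formula", call. = FALSE)
  structure(counts, class = "chem_formula")
}

#' @rdname parse_formula
#' @param f a `chem_formula` (or named count vector).
#' @return `format_formula()`: the canonical Hill-order string (C, H, then
#'   the remaining elements alphabetically).
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  ord <- c("C", "H", sort(setdiff(names(.ATOMIC_MASS), c("C", "H"))))
  out <- character(0)
  for (el in ord) {
    k <- f[[el]]
    if (k > 0L) out <- c(out, paste0(el, if (k > 1L) k else ""))
  }
  paste0(out, collapse = "")
}

# Coerce string or count vector to a validated chem_formula.
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- integer(length(.ATOMIC_MASS))
    names(counts) <- names(.ATOMIC_MASS)
    unknown <- setdiff(names(x), names(counts))
    if (length(unknown))
      stop("unsupported element(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    counts[names(x)] <- as.integer(round(x))
    if (any(counts < 0L)) stop("negative element counts", call. = FALSE)
    return(structure(counts, class = "chem_formula"))
  }
  stop("cannot interpret as a molecular formula", call. = FALSE)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

# Signed elementwise combination; `deltas` may take counts negative, in
# which case the caller decides whether that is an error.
formula_shift <- function(f, delta) {
  f <- unclass(as_formula(f))
  d <- integer(length(f)); names(d) <- names(f)
  d[names(delta)] <- d[names(delta)] + as.integer(delta)
  structure(f + d, class = "chem_formula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times monoisotopic atomic mass over the elements, using a
#' fixed internal table (C 12 exactly, H 1.00782503, N 14.00307401,
#' O 15.99491462, S 31.97207117, Cl 34.96885268).
#'
#' @param f formula string or `chem_formula`.
#' @return neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")       # 18.0106
#' monoisotopic_mass("C22H22O10") # 446.1213
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (any(f < 0L)) stop("negative element counts", call. = FALSE)
  sum(.ATOMIC_MASS * unclass(f))
}

#' Supported adducts
#'
#' The quasi-molecular ion species handled by [ion_mz()], with their ion
#' mode and the mass offset added to the neutral monoisotopic mass. The
#' electron mass is included in every charged species: protonation adds
#' m(H) - m(e) = 1.0072765 Da, deprotonation subtracts it, and the chloride
#' adduct adds m(Cl) + m(e).
#'
#' @return data frame with columns `adduct`, `mode` (`"+"`/`"-"`) and
#'   `offset` (Da).
#' @export
adducts <- function() {
  data.frame(
    adduct = c("[M+H]+", "[M-H]-", "[M+FA-H]-", "[M+Cl]-"),
    mode = c("+", "-", "-", "-"),
    offset = c(.PROTON_MASS,
               -.PROTON_MASS,
               .FORMIC_ACID - .PROTON_MASS,
               .ATOMIC_MASS[["Cl"]] + .ELECTRON_MASS),
    stringsAsFactors = FALSE
  )
}

# tolerant adduct label normalization: drop spaces, unify unicode minus
normalize_adduct <- function(adduct) {
  a <- gsub("[[:space:]]", "", adduct)
  a <- gsub("−", "-", a)
  a
}

#' Theoretical m/z of an adduct ion
#'
#' @param f neutral molecular formula (string or `chem_formula`).
#' @param adduct one of `"[M+H]+"`, `"[M-H]-"`, `"[M+FA-H]-"`, `"[M+Cl]-"`.
#' @return ion m/z in Da.
#' @export
#' @examples
#' ion_mz("C22H22O10", "[M+H]+")    # 447.1286
#' ion_mz("C40H64O12", "[M+FA-H]-") # 781.4380
#' ion_mz("C46H74O17", "[M+Cl]-")   # 933.4620
ion_mz <- function(f, adduct) {
  tab <- adducts()
  a <- normalize_adduct(adduct)
  i <- match(a, tab$adduct)
  if (is.na(i))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(tab$adduct, collapse = ", "), call. = FALSE)
  monoisotopic_mass(f) + tab$offset[i]
}

#' Relative mass error in parts per million
#'
#' `(measured - calc) / calc * 1e6`. Vectorized.
#'
#' @param measured,calc m/z values in Da; `calc` must be positive.
#' @return signed ppm error.
#' @export
ppm_error <- function(measured, calc) {
  if (any(calc <= 0)) stop("calculated m/z must be positive", call. = FALSE)
  (measured - calc) / calc * 1e6
}

#' Biotransformation rules
#'
#' The built-in phase-I/II modification library used by
#' [annotate_features()]: each rule is a signed element-count delta applied
#' to a parent formula. Deltas (Da): glucuronidation +C6H8O6 (+176.0321),
#' sulfation +SO3 (+79.9568), demethylation -CH2 (-14.0157), hydroxylation
#' +O (+15.9949), hydrogenation +H2 (+2.0157), deglycosylation -C6H10O5
#' (-162.0528).
#'
#' @return named list of signed integer element-count vectors with a
#'   `delta_mass` attribute on each element.
#' @export
modification_rules <- function() {
  rules <- list(
    glucuronidation = c(C = 6L, H = 8L, O = 6L),
    sulfation       = c(S = 1L, O = 3L),
    demethylation   = c(C = -1L, H = -2L),
    hydroxylation   = c(O = 1L),
    hydrogenation   = c(H = 2L),
    deglycosylation = c(C = -6L, H = -10L, O = -5L)
  )
  lapply(rules, function(d) {
    attr(d, "delta_mass") <- sum(.ATOMIC_MASS[names(d)] * d)
    d
  })
}

#' Apply a sequence of biotransformation rules to a parent formula
#'
#' @param parent formula string or `chem_formula`.
#' @param mods character vector of rule names (a multiset; order does not
#'   affect the result), or a list of signed element deltas.
#' @param rules rule library, as from [modification_rules()].
#' @return the modified `chem_formula`.
#' @export
#' @examples
#' format_formula(apply_modifications("C22H22O10", "glucuronidation"))
apply_modifications <- function(parent, mods,
                                rules = modification_rules()) {
  f <- as_formula(parent)
  if (is.character(mods)) {
    missing <- setdiff(mods, names(rules))
    if (length(missing))
      stop("unknown modification rule(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    mods <- rules[mods]
  }
  for (d in mods) f <- formula_shift(f, d)
  if (any(unclass(f) < 0L))
    stop("modification sequence yields negative element counts",
         call. = FALSE)
  f
}

# Enumerate all multisets of rule indices of size 0..max_depth
# (non-decreasing index sequences). Returns a list of integer vectors.
rule_multisets <- function(n_rules, max_depth) {
  out <- list(integer(0))
  frontier <- list(integer(0))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (ms in frontier) {
      lo <- if (length(ms)) ms[length(ms)] else 1L
      for (j in lo:n_rules) nxt[[length(nxt) + 1L]] <- c(ms, j)
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# Candidate table: every parent x modification-multiset x adduct whose
# element counts stay non-negative. Shared by the annotator and the
# synthetic feature generator.
candidate_table <- function(parents, rules = modification_rules(),
                            max_depth = 3L, adduct_set = adducts()) {
  stopifnot(is.list(parents), length(parents) > 0)
  if (is.null(names(parents)) || any(!nzchar(names(parents))))
    stop("parents must be a named list of formulas", call. = FALSE)
  multisets <- rule_multisets(length(rules), max_depth)
  rows <- vector("list", length(parents) * length(multisets))
  k <- 0L
  for (p in seq_along(parents)) {
    pf <- as_formula(parents[[p]])
    for (ms in multisets) {
      f <- pf
      ok <- TRUE
      for (j in ms) {
        f <- formula_shift(f, rules[[j]])
        if (any(unclass(f) < 0L)) { ok <- FALSE; break }
      }
      if (!ok) next
      k <- k + 1L
      rows[[k]] <- list(parent = names(parents)[p],
                        mods = paste(sort(names(rules)[ms]), collapse = "+"),
                        n_mods = length(ms),
                        formula = format_formula(f),
                        neutral_mass = monoisotopic_mass(f))
    }
  }
  base <- do.call(rbind, lapply(rows[seq_len(k)], function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  # cross with adducts
  out <- do.call(rbind, lapply(seq_len(nrow(adduct_set)), function(i) {
    d <- base
    d$adduct <- adduct_set$adduct[i]
    d$ion_mode <- adduct_set$mode[i]
    d$calc_mz <- d$neutral_mass + adduct_set$offset[i]
    d
  }))
  out[order(out$calc_mz), , drop = FALSE]
}

#' Annotate LC-MS features by parent x biotransformation x adduct search
#'
#' For each feature, enumerates every combination of parent compound,
#' modification multiset of size up to `max_depth`, and mode-matching
#' adduct; keeps the combinations whose theoretical m/z lies within
#' `tol_ppm` of the measured m/z, and ranks them by absolute ppm error,
#' then by number of modifications, then by parent name. Combinations that
#' would drive any element count negative are excluded.
#'
#' @param features data frame with columns `id`, `mz` and `ion_mode`
#'   (`"+"` or `"-"`).
#' @param parents named list (or named character vector) of parent
#'   formulas.
#' @param rules modification library, see [modification_rules()].
#' @param tol_ppm match tolerance in ppm (default 10).
#' @param max_depth maximum number of stacked modifications (default 3).
#' @param top_only if `TRUE`, keep only the best-ranked annotation per
#'   feature.
#' @return data frame with one row per retained candidate: `feature_id`,
#'   `mz`, `parent`, `modifications` (plus-joined, alphabetical),
#'   `n_mods`, `adduct`, `formula`, `calc_mz`, `ppm_error`, `rank`.
#' @export
annotate_features <- function(features, parents,
                              rules = modification_rules(),
                              tol_ppm = 10, max_depth = 3,
                              top_only = FALSE) {
  stopifnot(is.data.frame(features),
            all(c("id", "mz", "ion_mode") %in% names(features)))
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  if (is.character(parents)) parents <- as.list(parents)
  if (!length(parents)) stop("parents must be non-empty", call. = FALSE)
  cand <- candidate_table(parents, rules, max_depth)
  empty <- data.frame(feature_id = character(0), mz = numeric(0),
                      parent = character(0), modifications = character(0),
                      n_mods = integer(0), adduct = character(0),
                      formula = character(0), calc_mz = numeric(0),
                      ppm_error = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(features)) return(empty)
  res <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    mz <- features$mz[i]
    mode <- features$ion_mode[i]
    sub <- cand[cand$ion_mode == mode, , drop = FALSE]
    ppm <- (mz - sub$calc_mz) / sub$calc_mz * 1e6
    keep <- which(abs(ppm) <= tol_ppm)
    if (!length(keep)) next
    hit <- sub[keep, , drop = FALSE]
    hit$ppm_error <- ppm[keep]
    # round |ppm| for ranking so analytically identical masses reached by
    # different summation paths tie exactly and fall through to the
    # modification-count / parent-name tie-breaks
    ord <- order(round(abs(hit$ppm_error), 4), hit$n_mods, hit$parent,
                 hit$adduct)
    hit <- hit[ord, , drop = FALSE]
    res[[i]] <- data.frame(feature_id = features$id[i], mz = mz,
                           parent = hit$parent,
                           modifications = hit$mods,
                           n_mods = hit$n_mods, adduct = hit$adduct,
                           formula = hit$formula, calc_mz = hit$calc_mz,
                           ppm_error = hit$ppm_error,
                           rank = seq_len(nrow(hit)),
                           stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (top_only) out <- out[out$rank == 1L, , drop = FALSE]
  out
}

#' Neutral-loss library
#'
#' Common uncharged fragments lost in MS2 spectra of glycosides:
#' glucose residue C6H10O5 (162.0528), xylose residue C5H8O4 (132.0423),
#' deoxyhexose residue C6H10O4 (146.0579), methyl radical CH3 (15.0235),
#' carbon monoxide CO (27.9949) and methanol CH3OH (32.0262).
#'
#' @return named character vector of formulas.
#' @export
neutral_losses <- function() {
  c(glucose = "C6H10O5", xylose = "C5H8O4", deoxyhexose = "C6H10O4",
    CH3 = "CH3", CO = "CO", CH3OH = "CH4O")
}

#' Sequential neutral-loss fragmentation ladder
#'
#' Builds the expected fragment m/z sequence for a precursor ion losing a
#' given series of neutral fragments in turn: step k is the adduct ion of
#' the precursor formula minus the cumulative losses up to k.
#'
#' @param precursor neutral precursor formula.
#' @param adduct adduct label, see [adducts()].
#' @param losses character vector of loss names from [neutral_losses()]
#'   and/or explicit formula strings.
#' @return data frame of class `"fragment_ladder"` with columns `step`
#'   (0 = precursor ion), `loss`, `formula` (remaining neutral formula) and
#'   `mz`; m/z is strictly decreasing.
#' @export
#' @examples
#' fragment_ladder("C53H86O23", "[M+H]+",
#'                 c("xylose", "deoxyhexose", "glucose", "glucose"))
fragment_ladder <- function(precursor, adduct, losses = character(0)) {
  lib <- neutral_losses()
  f <- as_formula(precursor)
  steps <- list(list(step = 0L, loss = "", formula = format_formula(f),
                     mz = ion_mz(f, adduct)))
  for (k in seq_along(losses)) {
    name <- losses[k]
    lf <- if (name %in% names(lib)) parse_formula(lib[[name]])
          else parse_formula(name)
    f <- formula_shift(f, -unclass(lf))
    if (any(unclass(f) < 0L))
      stop("loss ", k, " ('", name, "') drives element counts negative",
           call. = FALSE)
    steps[[k + 1L]] <- list(step = k, loss = name,
                            formula = format_formula(f),
                            mz = ion_mz(f, adduct))
  }
  out <- do.call(rbind, lapply(steps, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  class(out) <- c("fragment_ladder", "data.frame")
  out
}

#' Match observed MS2 peaks against a fragmentation ladder
#'
#' Greedy nearest-ppm assignment: candidate (observed peak, ladder step)
#' pairs within `tol_ppm` are assigned in order of increasing absolute ppm
#' error, each observed peak and each ladder step used at most once.
#'
#' @param observed numeric vector of observed MS2 m/z values.
#' @param ladder a [fragment_ladder()] result.
#' @param tol_ppm match tolerance in ppm (default 20).
#' @return list with `matches` (data frame `step`, `ladder_mz`,
#'   `observed_mz`, `ppm_error`) and `coverage` (matched steps / total
#'   steps).
#' @export
match_fragments <- function(observed, ladder, tol_ppm = 20) {
  stopifnot(inherits(ladder, "fragment_ladder"), nrow(ladder) >= 1)
  pairs <- expand.grid(obs = seq_along(observed),
                       step = seq_len(nrow(ladder)))
  pairs$ppm <- (observed[pairs$obs] - ladder$mz[pairs$step]) /
    ladder$mz[pairs$step] * 1e6
  pairs <- pairs[abs(pairs$ppm) <= tol_ppm, , drop = FALSE]
  pairs <- pairs[order(abs(pairs$ppm)), , drop = FALSE]
  used_obs <- logical(length(observed))
  used_step <- logical(nrow(ladder))
  keep <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    o <- pairs$obs[i]; s <- pairs$step[i]
    if (!used_obs[o] && !used_step[s]) {
      used_obs[o] <- TRUE; used_step[s] <- TRUE
      keep <- c(keep, i)
    }
  }
  m <- pairs[keep, , drop = FALSE]
  matches <- data.frame(step = ladder$step[m$step],
                        ladder_mz = ladder$mz[m$step],
                        observed_mz = observed[m$obs],
                        ppm_error = m$ppm)
  matches <- matches[order(matches$step), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches, coverage = nrow(matches) / nrow(ladder))
}
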