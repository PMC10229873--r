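# elemental bookkeeping for the photosynthesis equation: a small formula /
# reaction grammar with fractional subscripts (biomass formulas like
# CH1.71O0.4N0.15P0.002), residual checking, and single-unknown solving.

#' Parse a chemical species formula
#'
#' Accepts element symbols with optional fractional subscripts (up to four
#' decimals) and an optional trailing charge sign (`+` or `-`, one unit of
#' charge per sign): `"CO2"`, `"NO3-"`, `"CH1.71O0.4N0.15P0.002"`, `"OH-"`,
#' `"P"`. Trailing digits always bind to the preceding element as a
#' subscript, never to the charge, so `"NO3-"` is N O3 with charge -1.
#'
#' @param text Formula string.
#' @return An object of class `chem_species`: list with `formula` (the input
#'   string), `elements` (named numeric counts) and `charge`.
#' @export
#' @examples
#' parse_species("NO3-")$charge
#' parse_species("CH1.71O0.4N0.15P0.002")$elements
parse_species <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) abort("empty species formula")
  core <- text
  charge <- 0
  m <- regmatches(text, regexpr("([+-]+)$", text))
  if (length(m) == 1 && nzchar(m)) {
    signs <- strsplit(m, "")[[1]]
    charge <- sum(ifelse(signs == "+", 1, -1))
    core <- sub("([+-]+)$", "", text)
  }
  pat <- "([A-Z][a-z]?)([0-9]+\\.?[0-9]*|\\.[0-9]+)?"
  starts <- gregexpr(pat, core)[[1]]
  toks <- regmatches(core, gregexpr(pat, core))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(core)) {
    abort(paste0("cannot parse formula: `", text, "`"))
  }
  el <- sub("([A-Z][a-z]?).*", "\\1", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  counts <- tapply(n, el, sum)
  structure(
    list(formula = text, elements = setNames(as.numeric(counts), names(counts)),
         charge = charge),
    class = "chem_species"
  )
}

#' Parse a reaction from its one-line text form
#'
#' Terms are separated by `+` surrounded by spaces (so species charges like
#' `NO3-` are unambiguous); the arrow is `->`; each term is an optional
#' numeric coefficient followed by a formula:
#' `"CO2 + 0.93 H2O + 0.15 NO3- + 0.002 P -> CH1.71O0.4N0.15P0.002 + 1.42 O2 + 0.15 OH-"`.
#'
#' @param text Reaction string.
#' @return An object of class `chem_reaction`: tibbles `reactants` and
#'   `products`, each with columns `coefficient`, `formula`, `species`
#'   (list of [parse_species()] results).
#' @export
parse_reaction <- function(text) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) abort("reaction must contain exactly one `->`")
  parse_side <- function(s) {
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0) abort("empty reaction side")
    purrr::map_dfr(terms, function(tm) {
      m <- regmatches(tm, regexec("^([0-9]+\\.?[0-9]*|\\.[0-9]+)?\\s*(\\S+)$", tm))[[1]]
      coefficient <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      if (coefficient <= 0) abort("stoichiometric coefficients must be positive")
      tibble(
        coefficient = coefficient, formula = m[3],
        species = list(parse_species(m[3]))
      )
    })
  }
  structure(
    list(reactants = parse_side(sides[1]), products = parse_side(sides[2])),
    class = "chem_reaction"
  )
}

#' @export
print.chem_reaction <- function(x, ...) {
  fmt <- function(side) {
    paste(
      ifelse(side$coefficient == 1, side$formula,
        paste(signif(side$coefficient, 6), side$formula)
      ),
      collapse = " + "
    )
  }
  cat(fmt(x$reactants), "->", fmt(x$products), "\n")
  invisible(x)
}

# per-side weighted element totals (including a pseudo-element "charge")
side_totals <- function(side) {
  tot <- c(charge = 0)
  for (i in seq_len(nrow(side))) {
    sp <- side$species[[i]]
    co <- side$coefficient[i]
    for (e in names(sp$elements)) {
      tot[e] <- (if (e %in% names(tot)) tot[[e]] else 0) + co * sp$elements[[e]]
    }
    tot["charge"] <- tot[["charge"]] + co * sp$charge
  }
  tot
}

#' Elemental and charge balance residuals of a reaction
#'
#' For each element (and for charge), the products-minus-reactants total:
#' zero everywhere means the reaction is balanced.
#'
#' @param rxn A `chem_reaction` from [parse_reaction()].
#' @return A tibble with columns `element` (element symbols plus `"charge"`)
#'   and `residual`.
#' @export
#' @examples
#' element_balance(parse_reaction("CO2 + H2O -> CH2O + O2"))
element_balance <- function(rxn) {
  stopifnot(inherits(rxn, "chem_reaction"))
  r <- side_totals(rxn$reactants)
  p <- side_totals(rxn$products)
  els <- union(names(r), names(p))
  els <- c(setdiff(sort(els), "charge"), "charge")
  tibble(
    element = els,
    residual = unname(vapply(els, function(e) {
      (if (e %in% names(p)) p[[e]] else 0) - (if (e %in% names(r)) r[[e]] else 0)
    }, numeric(1)))
  )
}

#' Solve for one unknown stoichiometric coefficient
#'
#' Given a reaction with every coefficient fixed except one, returns the
#' value of that coefficient that zeroes the balance residual of a chosen
#' element. Residuals are linear in each coefficient, so the solution is a
#' one-step rearrangement.
#'
#' @param rxn A `chem_reaction`; the unknown species' current coefficient is
#'   ignored.
#' @param unknown Formula string of the species whose coefficient is sought;
#'   must occur exactly once in the reaction.
#' @param element Element symbol to balance; must occur in the unknown
#'   species.
#' @return The solved coefficient.
#' @export
#' @examples
#' rxn <- parse_reaction("CO2 + H2O -> CH2O + O2")
#' solve_coefficient(rxn, "O2", "O") # 1
solve_coefficient <- function(rxn, unknown, element) {
  stopifnot(inherits(rxn, "chem_reaction"))
  hits <- list()
  for (side in c("reactants", "products")) {
    ix <- which(rxn[[side]]$formula == unknown)
    for (i in ix) hits[[length(hits) + 1]] <- list(side = side, i = i)
  }
  if (length(hits) != 1) {
    abort(paste0("`", unknown, "` must appear exactly once in the reaction"))
  }
  side <- hits[[1]]$side
  i <- hits[[1]]$i
  sp <- rxn[[side]]$species[[i]]
  count <- if (element == "charge") {
    sp$charge
  } else {
    v <- unname(sp$elements[element])
    if (is.na(v)) 0 else v
  }
  if (is.na(count) || count == 0) {
    abort(paste0("element `", element, "` absent from `", unknown, "`: unsolvable"))
  }
  # residual with the unknown term removed
  rxn0 <- rxn
  rxn0[[side]] <- rxn0[[side]][-i, ]
  bal <- element_balance(rxn0)
  r0 <- bal$residual[bal$element == element]
  if (length(r0) == 0) r0 <- 0
  sign <- if (side == "products") 1 else -1
  # solve r0 + sign * coeff * count = 0
  unname(-r0 / (sign * count))
}

#' The autotrophic photosynthesis reaction used by the model
#'
#' The growth stoichiometry for the *C. sorokiniana* biomass elemental
#' formula CH1.71O0.4N0.15P0.002, with nitrate as the nitrogen source:
#' `CO2 + 0.93 H2O + 0.15 NO3- + 0.002 P -> biomass + 1.42 O2 + 0.15 OH-`.
#' As printed, the oxygen balance carries a residual of about 0.01 from
#' rounding the O2 coefficient (1.415 -> 1.42).
#'
#' @param o2_coefficient O2 coefficient to use (default the printed 1.42).
#' @return A `chem_reaction`.
#' @export
#' @examples
#' round(solve_coefficient(photosynthesis_reaction(), "O2", "O"), 2)
photosynthesis_reaction <- function(o2_coefficient = 1.42) {
  parse_reaction(paste0(
    "CO2 + 0.93 H2O + 0.15 NO3- + 0.002 P -> ",
    "CH1.71O0.4N0.15P0.002 + ", o2_coefficient, " O2 + 0.15 OH-"
  ))
}
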