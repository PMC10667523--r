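#' Define a straight-chain fatty acid
#'
#' A fatty acid is identified by its shorthand `Cn:d`: `n` carbon atoms and
#' `d` C=C double bonds on a straight (unbranched) hydrocarbon chain with one
#' terminal methyl group and one carboxyl group. All chain-length and
#' saturation statistics in this package are derived from counting the CH3,
#' CH2, CH (olefinic) and COOH groups of such chains.
#'
#' @param carbons integer, total carbon atoms (the `n` in `Cn:d`); at least 4.
#' @param double_bonds integer, number of C=C bonds (the `d`); between 0 and
#'   `floor((carbons - 2) / 2)` — each double bond consumes two interior
#'   carbons.
#' @param name optional display name; defaults to the `n:d` shorthand.
#' @return an object of class `fatty_acid`.
#' @seealso [parse_fatty_acid()], [count_functional_groups()],
#'   [fatty_acid_hcl()], [fatty_acid_ds()]
#' @examples
#' oleic <- fatty_acid(18, 1, name = "oleic")
#' fatty_acid_hcl(oleic)
#' fatty_acid_ds(oleic)
#' @export
fatty_acid <- function(carbons, double_bonds = 0L, name = NULL) {
  stopifnot(length(carbons) == 1L, length(double_bonds) == 1L)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 4L) {
    stop("a straight-chain fatty acid needs at least 4 carbons, got ",
         carbons, call. = FALSE)
  }
  max_db <- (carbons - 2L) %/% 2L
  if (is.na(double_bonds) || double_bonds < 0L || double_bonds > max_db) {
    stop("double_bonds must lie in [0, ", max_db, "] for a C", carbons,
         " straight chain, got ", double_bonds, call. = FALSE)
  }
  structure(
    list(name = name %||% sprintf("%d:%d", carbons, double_bonds),
         carbons = carbons, double_bonds = double_bonds),
    class = "fatty_acid"
  )
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s (C%d:%d)\n", x$name, x$carbons, x$double_bonds))
  invisible(x)
}

# Vectorised shorthand parser: "16:0", "C18:2", "18:2(n-6)" -> carbons/d.
# The (n-x) double-bond-position suffix is accepted and discarded: position
# is invisible to functional-group counting.
parse_cn_d <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^C?([0-9]+):([0-9]+)\\s*(\\(n-[0-9]+\\))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("cannot parse fatty-acid shorthand: ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    carbons = vapply(m, function(g) as.integer(g[2]), 1L),
    double_bonds = vapply(m, function(g) as.integer(g[3]), 1L)
  )
}

#' Parse a fatty-acid shorthand string
#'
#' Accepts `"16:0"`, `"C16:0"` and `"18:2(n-6)"` style shorthand (the
#' `(n-x)` suffix identifies double-bond position, which does not affect
#' group counting and is discarded).
#'
#' @param x a single shorthand string.
#' @return a [fatty_acid()] object.
#' @export
parse_fatty_acid <- function(x) {
  stopifnot(length(x) == 1L)
  p <- parse_cn_d(x)
  fatty_acid(p$carbons, p$double_bonds)
}

#' Count CH3/CH2/CH/COOH groups of a fatty acid
#'
#' For a straight-chain acid CH3-(chain)-COOH the terminal methyl and
#' carboxyl are unique, each double bond turns two interior CH2 carbons into
#' olefinic CH carbons, and the remaining interior carbons are CH2. The four
#' counts always sum to the carbon number.
#'
#' @param fa a [fatty_acid()].
#' @return a list with integer fields `n_ch3`, `n_ch2`, `n_ch`, `n_cooh`.
#' @examples
#' count_functional_groups(fatty_acid(18, 1)) # 1, 14, 2, 1
#' @export
count_functional_groups <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  list(
    n_ch3 = 1L,
    n_ch2 = fa$carbons - 2L - 2L * fa$double_bonds,
    n_ch = 2L * fa$double_bonds,
    n_cooh = 1L
  )
}

#' Hydrocarbon chain length (HCL) of a fatty acid
#'
#' HCL is the total group count per terminal methyl,
#' (CH3 + CH2 + CH + COOH) / CH3. For a straight chain this equals the
#' carbon number exactly; the formulation in terms of functional groups is
#' what links the statistic to NIR band intensities.
#'
#' @param fa a [fatty_acid()].
#' @return dimensionless chain length.
#' @examples
#' fatty_acid_hcl(fatty_acid(16, 0)) # 16
#' @export
fatty_acid_hcl <- function(fa) {
  g <- count_functional_groups(fa)
  (g$n_ch3 + g$n_ch2 + g$n_ch + g$n_cooh) / g$n_ch3
}

#' Degree of saturation (DS) of a fatty acid
#'
#' DS is the CH2 fraction of the chain's CH + CH2 carbons,
#' CH2 / (CH + CH2) = (C - 2 - 2d) / (C - 2). It equals 1 exactly for a
#' saturated chain and decreases with every double bond.
#'
#' @param fa a [fatty_acid()].
#' @return dimensionless value in (0, 1].
#' @examples
#' fatty_acid_ds(fatty_acid(18, 1)) # 0.875
#' @export
fatty_acid_ds <- function(fa) {
  g <- count_functional_groups(fa)
  denom <- g$n_ch + g$n_ch2
  if (denom <= 0) {
    stop("degree of saturation is undefined for a C", fa$carbons,
         " chain (no CH/CH2 carbons)", call. = FALSE)
  }
  g$n_ch2 / denom
}

#' Per-fatty-acid property table
#'
#' Tabulates carbon counts, group counts, HCL and DS for a panel given as
#' shorthand strings. This is the vertex table for HCL/DS scatter plots.
#'
#' @param shorthand character vector of `Cn:d` shorthands.
#' @return a tibble with columns `fatty_acid`, `carbons`, `double_bonds`,
#'   `n_ch2`, `n_ch`, `hcl`, `ds`.
#' @export
fatty_acid_properties <- function(shorthand) {
  p <- parse_cn_d(shorthand)
  n_ch2 <- p$carbons - 2L - 2L * p$double_bonds
  n_ch <- 2L * p$double_bonds
  if (any(p$carbons < 4L) || any(n_ch2 < 0L)) {
    stop("invalid fatty acid in panel", call. = FALSE)
  }
  tibble::tibble(
    fatty_acid = sprintf("%d:%d", p$carbons, p$double_bonds),
    carbons = p$carbons,
    double_bonds = p$double_bonds,
    n_ch2 = n_ch2,
    n_ch = n_ch,
    hcl = as.numeric(p$carbons),
    ds = n_ch2 / (p$carbons - 2L)
  )
}

#' Default 16-fatty-acid liver panel
#'
#' Sixteen fatty acids commonly quantified in mouse liver by GC, including
#' the heptadecanoic internal standard (17:0, treated as an ordinary straight
#' chain). The exact panel is configurable everywhere a panel is accepted.
#'
#' @return a tibble as from [fatty_acid_properties()].
#' @export
default_fatty_acid_panel <- function() {
  fatty_acid_properties(c(
    "14:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2", "18:3",
    "20:1", "20:2", "20:3", "20:4", "20:5", "22:4", "22:5", "22:6"
  ))
}

#' Build a fatty-acid composition
#'
#' A composition records molar fractions of a set of distinct fatty acids
#' (the stand-in for a GC result) and, optionally, the sample's total lipid
#' content.
#'
#' @param fractions named numeric vector: names are `Cn:d` shorthands,
#'   values are molar fractions summing to 1 (tolerance 1e-9).
#' @param total_lipid optional total lipid content, mg per g tissue.
#' @return a tibble of class `fa_composition` with columns `fatty_acid`,
#'   `carbons`, `double_bonds`, `molar_fraction`, and attribute
#'   `total_lipid`.
#' @examples
#' fatty_acid_composition(c("16:0" = 0.5, "18:2" = 0.5))
#' @export
fatty_acid_composition <- function(fractions, total_lipid = NULL) {
  if (length(fractions) == 0L) stop("empty composition", call. = FALSE)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named by fatty-acid shorthand", call. = FALSE)
  }
  p <- parse_cn_d(names(fractions))
  key <- sprintf("%d:%d", p$carbons, p$double_bonds)
  if (anyDuplicated(key)) {
    stop("duplicated fatty acid in composition: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  f <- as.numeric(fractions)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("molar fractions must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("molar fractions must sum to 1 (got ", format(sum(f), digits = 12),
         ")", call. = FALSE)
  }
  out <- tibble::tibble(
    fatty_acid = key,
    carbons = p$carbons,
    double_bonds = p$double_bonds,
    molar_fraction = f
  )
  # validate each entry against the fatty_acid invariants
  for (i in seq_len(nrow(out))) fatty_acid(out$carbons[i], out$double_bonds[i])
  attr(out, "total_lipid") <- total_lipid
  class(out) <- c("fa_composition", class(out))
  out
}

#' Read / write a composition CSV
#'
#' Columns: `fatty_acid` (`Cn:d` shorthand), `molar_fraction`, and optional
#' `total_lipid_mg_per_g` (constant within a file).
#'
#' @param path file path.
#' @return for `read_composition`, an [fatty_acid_composition()].
#' @export
read_composition <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("fatty_acid", "molar_fraction") %in% names(d))) {
    stop("composition CSV needs columns fatty_acid, molar_fraction",
         call. = FALSE)
  }
  total <- if ("total_lipid_mg_per_g" %in% names(d)) {
    u <- unique(d$total_lipid_mg_per_g)
    if (length(u) != 1L) stop("total_lipid_mg_per_g must be constant",
                              call. = FALSE)
    u
  }
  fr <- d$molar_fraction
  names(fr) <- d$fatty_acid
  fatty_acid_composition(fr, total_lipid = total)
}

#' @rdname read_composition
#' @param comp an [fatty_acid_composition()].
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "fa_composition"))
  d <- tibble::tibble(fatty_acid = comp$fatty_acid,
                      molar_fraction = comp$molar_fraction)
  total <- attr(comp, "total_lipid")
  if (!is.null(total)) d$total_lipid_mg_per_g <- total
  readr::write_csv(d, path)
  invisible(path)
}

#' Tissue-level HCL and DS of a composition
#'
#' Two conventions are offered. `"pooled"` (default) forms the group-count
#' ratios over all molecules in the tissue: HCL is the molar-fraction-
#' weighted total group count per methyl (which reduces to the weighted mean
#' carbon number) and DS is total CH2 over total CH + CH2. `"weighted"`
#' instead takes molar-fraction-weighted means of the per-acid HCL and DS
#' values — the "linear combination of fatty-acid vectors" picture of the
#' HCL/DS plane. The two agree for HCL but differ slightly for DS because
#' longer chains carry more CH + CH2 carbons per molecule.
#'
#' @param comp an [fatty_acid_composition()].
#' @param mode `"pooled"` or `"weighted"`.
#' @return a one-row tibble with `hcl`, `ds`, `total_lipid` (NA when the
#'   composition carries none) and `mode`.
#' @examples
#' comp <- fatty_acid_composition(c("16:0" = 0.5, "18:2" = 0.5))
#' composition_profile(comp) # HCL 17, DS 26/30
#' @export
composition_profile <- function(comp, mode = c("pooled", "weighted")) {
  stopifnot(inherits(comp, "fa_composition"))
  mode <- match.arg(mode)
  f <- comp$molar_fraction
  n_ch2 <- comp$carbons - 2L - 2L * comp$double_bonds
  n_ch <- 2L * comp$double_bonds
  hcl <- sum(f * comp$carbons) # = sum(f*(1 + n_ch2 + n_ch + 1)) / sum(f*1)
  ds <- if (mode == "pooled") {
    sum(f * n_ch2) / sum(f * (n_ch + n_ch2))
  } else {
    sum(f * n_ch2 / (n_ch + n_ch2))
  }
  tibble::tibble(
    hcl = hcl, ds = ds,
    total_lipid = attr(comp, "total_lipid") %||% NA_real_,
    mode = mode
  )
}

#' Assemble HCL/DS scatter data
#'
#' Pairs tissue-level (HCL, DS) points with the per-fatty-acid vertex
#' coordinates of a panel, ready for plotting on the HCL (x) / DS (y)
#' plane. Under the `"weighted"` profile convention every tissue point is a
#' convex combination of the panel vertices and therefore lies inside their
#' convex hull; pooled-DS points can fall marginally below a hull edge (the
#' pooled ratio weights longer chains more heavily).
#'
#' @param profiles a tibble with columns `hcl`, `ds` and optionally `group`
#'   (as produced by [composition_profile()] row-binding).
#' @param panel a panel tibble from [fatty_acid_properties()] /
#'   [default_fatty_acid_panel()].
#' @return a list of class `hcl_ds_scatter` with tibbles `points`
#'   (`group`, `hcl`, `ds`) and `vertices` (`fatty_acid`, `hcl`, `ds`).
#' @export
hcl_ds_scatter_data <- function(profiles, panel = default_fatty_acid_panel()) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L,
    all(c("hcl", "ds") %in% names(profiles)),
    is.data.frame(panel), nrow(panel) >= 1L)
  points <- tibble::tibble(
    group = if ("group" %in% names(profiles)) as.character(profiles$group)
            else sprintf("sample%d", seq_len(nrow(profiles))),
    hcl = profiles$hcl,
    ds = profiles$ds
  )
  vertices <- tibble::tibble(
    fatty_acid = panel$fatty_acid, hcl = panel$hcl, ds = panel$ds
  )
  structure(list(points = points, vertices = vertices),
            class = "hcl_ds_scatter")
}
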