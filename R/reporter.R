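#' Define a translation reporter construct
#'
#' A reporter construct is a geometric description of an open reading frame
#' carrying an N-terminal array of SunTag epitopes (bound co-translationally
#' by scFv-GFP) and, optionally, PP7 hairpins in the 3' UTR for mRNA
#' labeling.  Positions are 1-based codon indices; position 0 means
#' "initiating, nothing synthesized yet".
#'
#' @param name Identifier for the construct.
#' @param orf_length_codons Total ORF length \eqn{L} in codons.
#' @param epitope_positions Strictly increasing codon indices at which each
#'   epitope's last codon is translated.
#' @param exit_tunnel_codons Codons between peptide-bond formation and the
#'   epitope clearing the ribosome exit tunnel (antibody accessibility lag).
#' @param hairpin_count Number of PP7 hairpins in the 3' UTR.
#'
#' @return An object of class `reporter_construct`.
#' @examples
#' rc <- reporter_preset("kif18b_suntag24")
#' exposed_epitope_fraction(c(0, 374, rc$orf_length_codons), rc)
#' @export
reporter_construct <- function(name, orf_length_codons, epitope_positions,
                               exit_tunnel_codons = 35, hairpin_count = 24) {
  L <- as.integer(orf_length_codons)
  e <- as.integer(epitope_positions)
  d <- as.integer(exit_tunnel_codons)
  if (length(L) != 1L || is.na(L) || L < 1L) abort("orf_length_codons must be a positive integer")
  if (length(e) < 1L) abort("at least one epitope position is required")
  if (any(diff(e) <= 0L)) abort("epitope positions must be strictly increasing")
  if (any(e < 1L | e > L)) abort("epitope positions must lie in [1, L]")
  if (is.na(d) || d < 0L) abort("exit_tunnel_codons must be nonnegative")
  if (hairpin_count < 0) abort("hairpin_count must be nonnegative")
  structure(
    list(name = as.character(name), orf_length_codons = L,
         epitope_positions = e, exit_tunnel_codons = d,
         hairpin_count = as.integer(hairpin_count)),
    class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat(sprintf("<reporter_construct> %s: L = %d codons, %d epitopes (first visible at %d), tunnel offset %d, %d hairpins\n",
              x$name, x$orf_length_codons, length(x$epitope_positions),
              x$epitope_positions[1] + x$exit_tunnel_codons,
              x$exit_tunnel_codons, x$hairpin_count))
  invisible(x)
}

# 24x SunTag array spans ~634 codons => uniform epitope spacing 26.4 codons
.suntag_epitopes <- function(k, spacing = 26.4) as.integer(round(spacing * seq_len(k)))

#' Built-in reporter construct presets
#'
#' `kif18b_suntag24` is the workhorse reporter: a 24x SunTag array followed
#' by the Kif18b coding sequence (2.5 kb), 1467 codons in total, with 24
#' PP7 hairpins.  `suntag5` / `suntag10` shorten the array, `emi1_long_5utr`
#' shares the main reporter geometry (its 5' UTR only changes initiation),
#' `xbp1_pause` appends a pause cassette near the 3' end, and
#' `u2af2_codonopt` is a shorter codon-optimized ORF.
#'
#' @param name One of `"kif18b_suntag24"`, `"suntag5"`, `"suntag10"`,
#'   `"emi1_long_5utr"`, `"xbp1_pause"`, `"u2af2_codonopt"`.
#' @return A [reporter_construct()].
#' @export
reporter_preset <- function(name = c("kif18b_suntag24", "suntag5", "suntag10",
                                     "emi1_long_5utr", "xbp1_pause",
                                     "u2af2_codonopt")) {
  name <- match.arg(name)
  switch(name,
    kif18b_suntag24 = reporter_construct(name, 1467L, .suntag_epitopes(24)),
    suntag5         = reporter_construct(name, 965L, .suntag_epitopes(5)),
    suntag10        = reporter_construct(name, 1097L, .suntag_epitopes(10)),
    emi1_long_5utr  = reporter_construct(name, 1467L, .suntag_epitopes(24)),
    xbp1_pause      = reporter_construct(name, 1530L, .suntag_epitopes(24)),
    u2af2_codonopt  = reporter_construct(name, 1109L, .suntag_epitopes(24)))
}

#' Fraction of epitopes exposed by a ribosome at a given position
#'
#' The per-ribosome intensity function \eqn{f(x)}: a ribosome whose active
#' site is at codon \eqn{x} has completed all epitopes \eqn{e_i} with
#' \eqn{e_i + \Delta \le x} (where \eqn{\Delta} is the exit-tunnel offset),
#' each already bound by a fluorescent antibody.  Intensity is expressed as
#' a fraction of the full nascent chain, so `1` is one mature protein
#' equivalent.  The default is the exact step form; `mode = "continuum"`
#' returns the linear ramp between the first and last visible epitope used
#' by the runoff model.
#'
#' @param position Codon position(s) in `[0, L]` (0 = initiating).
#' @param construct A [reporter_construct()].
#' @param mode `"discrete"` (step function, default) or `"continuum"`
#'   (linear ramp).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
exposed_epitope_fraction <- function(position, construct, mode = c("discrete", "continuum")) {
  mode <- match.arg(mode)
  L <- construct$orf_length_codons
  if (any(!is.finite(position)) || any(position < 0) || any(position > L))
    abort("position must lie in [0, L]")
  vis <- construct$epitope_positions + construct$exit_tunnel_codons
  if (mode == "discrete") {
    vapply(position, function(x) mean(vis <= x), numeric(1))
  } else {
    v1 <- vis[1]; vk <- vis[length(vis)]
    if (vk == v1) return(as.numeric(position >= v1))
    pmin(1, pmax(0, (position - v1) / (vk - v1)))
  }
}

#' Translation-site intensity from a set of ribosome positions
#'
#' The noiseless forward model: site intensity is the sum over ribosomes of
#' the exposed-epitope fraction at each position, in single-mature-protein
#' units.  Additive in ribosomes; an empty site has intensity 0.
#'
#' @param positions Codon positions of all ribosomes on the mRNA (may be
#'   empty).
#' @inheritParams exposed_epitope_fraction
#' @return A single nonnegative number.
#' @export
site_intensity <- function(positions, construct, mode = c("discrete", "continuum")) {
  if (length(positions) == 0) return(0)
  if (any(positions < 1)) abort("ribosome positions must lie in [1, L]")
  sum(exposed_epitope_fraction(positions, construct, mode))
}

#' Mean positional intensity correction
#'
#' The expected per-ribosome intensity for a ribosome placed uniformly on
#' the ORF, \eqn{\bar c = L^{-1}\sum_{x=1}^{L} f(x)}.  Dividing a site
#' intensity by \eqn{\bar c} corrects for ribosomes near the 5' end having
#' synthesized only part of the epitope array.
#'
#' @inheritParams exposed_epitope_fraction
#' @return A fraction in `(0, 1]`.
#' @export
mean_positional_correction <- function(construct, mode = c("discrete", "continuum")) {
  mode <- match.arg(mode)
  L <- construct$orf_length_codons
  mean(exposed_epitope_fraction(seq_len(L), construct, mode))
}

#' Estimate ribosome number from translation-site intensity
#'
#' Inverts the forward intensity model in expectation for uniformly
#' positioned ribosomes: \eqn{N = I / \bar c}.  Small negative intensities
#' from background subtraction are clamped to zero.
#'
#' @param intensity Site intensity (single-mature-protein units); vectorized.
#' @param construct A [reporter_construct()].
#' @param clamp_tol Negative values above `-clamp_tol` are clamped to 0.
#' @return A tibble with columns `intensity`, `ribosomes` (real-valued) and
#'   `ribosomes_rounded`.
#' @export
estimate_ribosome_count <- function(intensity, construct, clamp_tol = 0.5) {
  if (any(!is.finite(intensity))) abort("intensity must be finite")
  if (any(intensity < -clamp_tol)) abort("intensity far below zero; check background subtraction")
  intensity <- pmax(intensity, 0)
  cbar <- mean_positional_correction(construct)
  tibble::tibble(intensity = intensity,
                 ribosomes = intensity / cbar,
                 ribosomes_rounded = as.integer(round(intensity / cbar)))
}

#' Label stoichiometry of the mRNA channel
#'
#' Describes how many fluorophores decorate one mRNA relative to the
#' single-protein intensity standard: PP7 coat protein binds each hairpin
#' as a dimer, and each PP7 carries tandem fluorophores, but hairpin
#' occupancy may be partial.
#'
#' @param hairpin_count Hairpins in the 3' UTR.
#' @param pp7_per_hairpin PP7 proteins bound per hairpin (dimer = 2).
#' @param fluorophores_per_pp7 Fluorophores fused to each PP7.
#' @param occupancy Fraction of hairpins occupied, in `[0, 1]`.
#' @param reference_fluorophores Fluorophore count of the single-protein
#'   intensity standard (24 for a fully decorated 24x epitope array).
#' @return An object of class `label_stoichiometry`.
#' @export
label_stoichiometry <- function(hairpin_count = 24, pp7_per_hairpin = 2,
                                fluorophores_per_pp7 = 2, occupancy = 1,
                                reference_fluorophores = 24) {
  if (occupancy < 0 || occupancy > 1) abort("occupancy must lie in [0, 1]")
  if (any(c(hairpin_count, pp7_per_hairpin, fluorophores_per_pp7,
            reference_fluorophores) < 0)) abort("counts must be nonnegative")
  structure(list(hairpin_count = hairpin_count, pp7_per_hairpin = pp7_per_hairpin,
                 fluorophores_per_pp7 = fluorophores_per_pp7, occupancy = occupancy,
                 reference_fluorophores = reference_fluorophores),
            class = "label_stoichiometry")
}

#' Expected brightness ratio of an mRNA spot to the single-protein standard
#'
#' @param stoich A [label_stoichiometry()].
#' @return Expected fold brightness (positive real).
#' @examples
#' expected_label_ratio(label_stoichiometry(occupancy = 1))   # 4-fold
#' expected_label_ratio(label_stoichiometry(occupancy = 0.5)) # 2-fold
#' @export
expected_label_ratio <- function(stoich) {
  if (stoich$reference_fluorophores == 0) abort("reference_fluorophores must be positive")
  with(stoich, hairpin_count * pp7_per_hairpin * fluorophores_per_pp7 * occupancy /
         reference_fluorophores)
}

#' Read or write a reporter construct definition
#'
#' Constructs serialize to YAML or JSON with keys `name`,
#' `orf_length_codons`, `epitopes`, `exit_tunnel_codons`, `hairpin_count`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param construct A [reporter_construct()] (for writing).
#' @return `read_construct()` returns a [reporter_construct()];
#'   `write_construct()` returns `path` invisibly.
#' @export
read_construct <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  reporter_construct(x$name, x$orf_length_codons, x$epitopes,
                     x$exit_tunnel_codons %||% 35, x$hairpin_count %||% 24)
}

#' @rdname read_construct
#' @export
write_construct <- function(construct, path) {
  x <- list(name = construct$name,
            orf_length_codons = construct$orf_length_codons,
            epitopes = construct$epitope_positions,
            exit_tunnel_codons = construct$exit_tunnel_codons,
            hairpin_count = construct$hairpin_count)
  if (grepl("\\.json$", path)) jsonlite::write_json(x, path, auto_unbox = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
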