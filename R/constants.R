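# Shared experimental constants: the published acquisition parameters the
# pipeline defaults reproduce, and the AGP2 expression construct.

#' Relaxation delay schedules (ms)
#'
#' The inversion-recovery (T1) and CPMG-type (T2) relaxation delay grids
#' used for the backbone \eqn{^{15}}N measurements on the AGP2--UCN-01
#' complex.  The synthetic decay generator samples on these grids so that
#' estimator-recovery properties are assessed under the real sampling
#' design.
#'
#' @return Numeric vector of delays in milliseconds.
#' @export
t1_delay_grid_ms <- function() {
  c(10, 50, 100, 200, 400, 600, 800, 1000, 1200, 1500, 1800, 2000, 2500)
}

#' @rdname t1_delay_grid_ms
#' @export
t2_delay_grid_ms <- function() {
  c(10, 48, 64, 80, 96, 128, 160, 192, 240, 320)
}

# Raw printed sequence of the full-length AGP2 expression construct:
# His6 3C-cleavable tag (17 aa), GP scar left by 3C cleavage, then the
# 183-aa mature protein (C149R variant).  Mature numbering starts at the
# Gln of "QIPLC".
.agp2_raw_sequence <- paste0(
  "MAHHHHHHSSGLEVLFQGP",
  "QIPLCANLVPVPITNATLDRITGKWFYIASAFR",
  "NEEYNKSVQEIQATFFYFTPNKTEDTIFLREYQTRQNQCF",
  "YNSSYLNVQRENGTVSRYEGGREHVAHLLFLRDTKTLMF",
  "GSYLDDEKNWGLSFYADKPETTKEQLGEFYEALDCLRIPR",
  "SDVMYTDWKKDKCEPLEKQHEKERKQEEGES"
)

#' AGP2 expression constructs
#'
#' Construct definitions for recombinant alpha-1-acid glycoprotein variant 2
#' (AGP2, C149R): the full-length construct (`agp2_construct()`, mature
#' residues 1--183 after tag cleavage) and the C-terminally truncated form
#' used for the NMR and crystallographic work (`agp2_truncated_construct()`,
#' a stop codon at mature position 173 removes the last 11 residues).
#'
#' The raw sequence carries a cleavable N-terminal His6 tag (raw positions
#' 1--17) and a "GP" cloning scar that remains after 3C protease cleavage;
#' the scar is reported at mature positions -1 and 0 so that mature
#' numbering matches the literature (Cys5, Glu64, Arg90, ...).
#'
#' @return A [construct()] object.
#' @seealso [cleave_construct()], [apply_truncation()]
#' @export
agp2_construct <- function() {
  construct(.agp2_raw_sequence, tag_region = c(1L, 17L), extension = "GP")
}

#' @rdname agp2_construct
#' @export
agp2_truncated_construct <- function() {
  construct(.agp2_raw_sequence, tag_region = c(1L, 17L), extension = "GP",
            stop_position = 173L)
}
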