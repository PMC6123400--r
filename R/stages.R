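# Ordered germ-cell stage codes and helpers. The total order is load-bearing:
# every "before"/"after" comparison in the MSCI rules and the consecutive-stage
# transition logic uses this sequence.

#' Ordered spermatogenic stage codes
#'
#' The twenty profiled germ-cell stages in developmental order: differentiating
#' spermatogonia (A1, In, BS, BG2), preleptotene spermatocytes (G1, ePL, mPL,
#' lPL), meiotic prophase I and divisions (L, Z, eP, mP, lP, D, MI, MII), and
#' round spermatid steps (RS2, RS4, RS6, RS8).
#'
#' @return Character vector of the 20 stage codes in developmental order.
#' @export
stage_codes <- function() {
  c("A1", "In", "BS", "BG2", "G1", "ePL", "mPL", "lPL", "L", "Z",
    "eP", "mP", "lP", "D", "MI", "MII", "RS2", "RS4", "RS6", "RS8")
}

#' Position of stages in the developmental order
#'
#' @param stage Character vector of stage codes.
#' @return Integer positions (1 = A1 ... 20 = RS8).
#' @export
stage_index <- function(stage) {
  idx <- match(stage, stage_codes())
  if (anyNA(idx)) {
    sd_stop(sprintf("unknown stage code(s): %s",
                    paste(unique(stage[is.na(idx)]), collapse = ", ")),
            "spermdyn_validation_error")
  }
  idx
}

#' Default mapping of stages to expression clusters C1-C7
#'
#' Mitotic spermatogonia through early preleptotene fall in C1, S-phase
#' preleptotene in C2, leptotene/zygotene in C3, pachytene in C4,
#' diplotene through early round spermatids in C5, and later spermatid
#' steps in C6/C7.
#'
#' @return Named character vector mapping each stage code to a cluster label.
#' @export
stage_cluster_map <- function() {
  c(A1 = "C1", In = "C1", BS = "C1", BG2 = "C1", G1 = "C1", ePL = "C1",
    mPL = "C2", lPL = "C2", L = "C3", Z = "C3",
    eP = "C4", mP = "C4", lP = "C4",
    D = "C5", MI = "C5", MII = "C5", RS2 = "C5",
    RS4 = "C6", RS6 = "C6", RS8 = "C7")
}

# Stage index sets used by the sex-linked classifier. "Before eP" excludes eP,
# "after MII" includes MII, "before MII" excludes MII.
stages_before_ep <- function() stage_codes()[1:10]    # A1 .. Z
stages_pachytene <- function() stage_codes()[11:13]   # eP, mP, lP
stages_postmeiotic <- function() stage_codes()[16:20] # MII .. RS8
stages_before_mii <- function() stage_codes()[1:15]   # A1 .. MI
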