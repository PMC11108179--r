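#' Gene and quinone inventories of the flux model
#'
#' `REDUCTASE_GENES` are the terminal-reductase catalytic subunits tracked
#' by a [genotype()]; `QUINONE_GENES` the quinone biosynthesis genes;
#' `QUINONE_SPECIES` the membrane quinone species (ubiquinone, menaquinone,
#' demethylmenaquinone).
#'
#' @name gene-inventories
#' @export
REDUCTASE_GENES <- c("napA", "narG", "narZ", "frdA", "dmsA", "torA", "torYZ")

#' @rdname gene-inventories
#' @export
QUINONE_GENES <- c("menA", "ubiC", "ubiE")

#' @rdname gene-inventories
#' @export
QUINONE_SPECIES <- c("UQ", "MQ", "DMQ")

#' Define a genotype for the electron transport chain model
#'
#' Presence/absence flags for the catalytic subunits of the terminal
#' reductases (NapA, NarG, NarZ for nitrate; FrdA for fumarate; DmsA for
#' DMSO; TorA plus a TorYZ-like aggregate for TMAO) and for the quinone
#' biosynthesis genes. Which quinone species a genotype can make follows
#' deterministically from the biosynthesis genes: loss of `menA` removes
#' menaquinone and demethylmenaquinone, loss of `ubiC` removes ubiquinone,
#' and loss of `ubiE` removes ubiquinone and demethylmenaquinone.
#'
#' @param napA,narG,narZ,frdA,dmsA,torA,torYZ Logical; reductase catalytic
#'   subunit present.
#' @param menA,ubiC,ubiE Logical; quinone biosynthesis gene present.
#' @param preset Optional organism tag carried along for display.
#' @return A `genotype` object (named logical vector).
#' @seealso [genotype_preset()], [knockout()], [quinones_present()]
#' @export
genotype <- function(napA = TRUE, narG = TRUE, narZ = TRUE, frdA = TRUE,
                     dmsA = TRUE, torA = TRUE, torYZ = TRUE,
                     menA = TRUE, ubiC = TRUE, ubiE = TRUE,
                     preset = "custom") {
  flags <- c(napA = napA, narG = narG, narZ = narZ, frdA = frdA,
             dmsA = dmsA, torA = torA, torYZ = torYZ,
             menA = menA, ubiC = ubiC, ubiE = ubiE)
  if (!is.logical(flags) || anyNA(flags)) {
    stop("all genotype flags must be TRUE or FALSE", call. = FALSE)
  }
  structure(flags, preset = preset, class = "genotype")
}

#' Organism genotype presets
#'
#' `"wildtype"` (alias `"C_portucalensis"`): all reductases and all three
#' quinones, as in the soil isolate with the fully branched chain.
#' `"P_aeruginosa"`: ubiquinone only, one respiratory nitrate reductase
#' (NarG) plus the periplasmic NapA, no fumarate/DMSO/TMAO reductases.
#' `"abiotic"`: no genes at all - a cell-free control in which only the
#' direct chemical reaction between reduced phenazine and the terminal
#' electron acceptor can run.
#'
#' @param name One of `"wildtype"`, `"C_portucalensis"`, `"P_aeruginosa"`,
#'   `"abiotic"`.
#' @export
genotype_preset <- function(name = c("wildtype", "C_portucalensis",
                                     "P_aeruginosa", "abiotic")) {
  name <- match.arg(name)
  switch(name,
    wildtype = ,
    C_portucalensis = genotype(preset = "C_portucalensis"),
    P_aeruginosa = genotype(narZ = FALSE, frdA = FALSE, dmsA = FALSE,
                            torA = FALSE, torYZ = FALSE, menA = FALSE,
                            preset = "P_aeruginosa"),
    abiotic = genotype(napA = FALSE, narG = FALSE, narZ = FALSE, frdA = FALSE,
                       dmsA = FALSE, torA = FALSE, torYZ = FALSE,
                       menA = FALSE, ubiC = FALSE, ubiE = FALSE,
                       preset = "abiotic")
  )
}

#' Knock out genes in a genotype
#'
#' @param g A [genotype()].
#' @param ... Gene names (character) to set absent, e.g.
#'   `knockout(g, "narG", "narZ")`.
#' @export
knockout <- function(g, ...) {
  stopifnot(inherits(g, "genotype"))
  genes <- unlist(list(...), use.names = FALSE)
  bad <- setdiff(genes, names(g))
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  g[genes] <- FALSE
  attr(g, "preset") <- paste0(attr(g, "preset"), " ", paste(genes, collapse = ""), "-KO")
  g
}

#' Quinone species available to a genotype
#'
#' @param g A [genotype()].
#' @return Named logical vector over `UQ`, `MQ`, `DMQ`.
#' @export
quinones_present <- function(g) {
  stopifnot(inherits(g, "genotype"))
  c(UQ = unname(g["ubiC"] && g["ubiE"]),
    MQ = unname(g["menA"]),
    DMQ = unname(g["menA"] && g["ubiE"]))
}

#' @export
print.genotype <- function(x, ...) {
  absent <- names(x)[!x]
  cat(sprintf("<genotype> %s | absent: %s\n", attr(x, "preset"),
              if (length(absent)) paste(absent, collapse = ", ") else "none"))
  invisible(x)
}

#' Default quinone-reductase compatibility matrix
#'
#' Which quinol species each terminal reductase can oxidize. The respiratory
#' nitrate reductases (NarG, NarZ) accept all three quinols; the periplasmic
#' nitrate reductase (NapA) uses ubiquinol and menaquinol but not
#' demethylmenaquinol; the fumarate reductase does not engage ubiquinol; the
#' DMSO/TMAO reductases default to (demethyl)menaquinol.
#'
#' @return Logical matrix, rows = reductases, columns = `UQ`, `MQ`, `DMQ`.
#' @export
default_compatibility <- function() {
  m <- matrix(FALSE, nrow = length(REDUCTASE_GENES), ncol = length(QUINONE_SPECIES),
              dimnames = list(REDUCTASE_GENES, QUINONE_SPECIES))
  m["narG", ] <- TRUE
  m["narZ", ] <- TRUE
  m["napA", c("UQ", "MQ")] <- TRUE
  m["frdA", c("MQ", "DMQ")] <- TRUE
  m["dmsA", c("MQ", "DMQ")] <- TRUE
  m["torA", c("MQ", "DMQ")] <- TRUE
  m["torYZ", c("MQ", "DMQ")] <- TRUE
  m
}

#' Terminal reductases serving an electron acceptor
#'
#' Nitrate can be reduced by any of NapA, NarG, NarZ; fumarate only by FrdA;
#' DMSO by DmsA; TMAO by TorA, the promiscuous DmsA, and a TorYZ-like
#' aggregate of additional TMAO reductases.
#'
#' @param acceptor One of `"nitrate"`, `"fumarate"`, `"DMSO"`, `"TMAO"`.
#' @return Character vector of reductase gene names.
#' @export
acceptor_reductases <- function(acceptor) {
  switch(acceptor,
    nitrate = c("napA", "narG", "narZ"),
    fumarate = "frdA",
    DMSO = "dmsA",
    TMAO = c("torA", "dmsA", "torYZ"),
    stop("unknown terminal electron acceptor: '", acceptor,
         "' (expected nitrate, fumarate, DMSO or TMAO)", call. = FALSE)
  )
}

#' Pregrowth condition and reductase expression weights
#'
#' The pregrowth condition sets which reductases are expressed going into
#' the assay. Oxic (shaking) pregrowth leaves the stationary-phase-regulated
#' NarZ dominant with the periplasmic NapA effectively absent; hypoxic
#' (standing) pregrowth makes the Fnr-regulated NarG dominant with NarZ and
#' NapA partially expressed. The non-nitrate reductases are taken as fully
#' expressed under both conditions. Weights are free calibration knobs in
#' `[0, 1]` and can be overridden.
#'
#' @param label `"oxic"` or `"hypoxic"`.
#' @param weights Optional named numeric vector overriding individual
#'   reductase weights.
#' @return A `pregrowth_condition` object.
#' @export
pregrowth_condition <- function(label = c("hypoxic", "oxic"), weights = NULL) {
  label <- match.arg(label)
  w <- setNames(rep(1, length(REDUCTASE_GENES)), REDUCTASE_GENES)
  if (label == "oxic") {
    w[c("narZ", "narG", "napA")] <- c(1, 0.2, 0)
  } else {
    w[c("narZ", "narG", "napA")] <- c(0.75, 1, 0.75)
  }
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), REDUCTASE_GENES)
    if (length(bad)) stop("unknown reductase(s): ", paste(bad, collapse = ", "), call. = FALSE)
    w[names(weights)] <- weights
  }
  if (any(w < 0 | w > 1)) stop("expression weights must lie in [0, 1]", call. = FALSE)
  structure(list(label = label, weights = w), class = "pregrowth_condition")
}
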