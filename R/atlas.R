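## Fixed 96-entry region vocabulary: 90 AAL-style cerebral regions plus 6
## brainstem regions (bilateral medulla oblongata, midbrain, pons), each
## mapped to one of the display lobe groups.
.AAL_BASE <- data.frame(
  stem = c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
           "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
           "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area",
           "Olfactory", "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus",
           "Insula", "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post",
           "Hippocampus", "ParaHippocampal", "Amygdala", "Calcarine",
           "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid",
           "Occipital_Inf", "Fusiform", "Postcentral", "Parietal_Sup",
           "Parietal_Inf", "SupraMarginal", "Angular", "Precuneus",
           "Paracentral_Lobule", "Caudate", "Putamen", "Pallidum",
           "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
           "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"),
  lobe = c("SOM", "FL", "FL", "FL", "FL", "Broca", "Broca", "FL", "SOM",
           "SOM", "FL", "FL", "FL", "FL", "INS", "CG", "CG", "CG", "Hip",
           "Hip", "Amy", "OL", "OL", "OL", "OL", "OL", "OL", "TL", "SOM",
           "PL", "PL", "PL", "PL", "PL", "SOM", "Str", "Str", "Str",
           "Tha", "TL", "TL", "TL", "TL", "TL", "TL"),
  stringsAsFactors = FALSE)

.BRAINSTEM <- data.frame(
  stem = c("Medulla", "Pons", "Midbrain"),
  lobe = "BS", stringsAsFactors = FALSE)

#' The default 96-region atlas vocabulary
#'
#' Region table underlying the synthetic atlas: 90 AAL-style cerebral
#' regions (left/right pairs) followed by 6 brainstem regions (bilateral
#' medulla oblongata, pons, midbrain), each with a lobe grouping from the
#' display vocabulary (BS, Str, Tha, Amy, Hip, CG, FL, PL, OL, INS, SOM,
#' TL, Broca).
#'
#' For reduced atlases (\code{n < 96}, used for fast tests and small
#' simulations) the table keeps the disease-relevant vocabulary first -
#' brainstem, striatum, then the default affected neocortex regions - so
#' that a truncated atlas still hosts the seed and the lagged groups.
#'
#' @param n number of regions to return, 1..96 (default all 96).
#' @return data.frame with columns \code{region_id}, \code{name},
#'   \code{lobe_group}.
#' @export
atlasRegionTable <- function(n = 96L) {
  both <- rbind(.AAL_BASE, .BRAINSTEM)
  tab <- data.frame(
    region_id = seq_len(2L * nrow(both)),
    name = as.vector(t(outer(both$stem, c("_L", "_R"), paste0))),
    lobe_group = rep(both$lobe, each = 2L),
    stringsAsFactors = FALSE)
  if (n < 1L || n > nrow(tab))
    stop("n must lie in 1..", nrow(tab))
  if (n < nrow(tab)) {
    priority <- c(which(tab$lobe_group == "BS"),
                  which(tab$lobe_group == "Str"),
                  which(tab$name %in% c("Frontal_Mid_L", "Frontal_Mid_R",
                                        "Occipital_Mid_L", "Occipital_Mid_R",
                                        "Parietal_Sup_L", "Parietal_Sup_R")))
    tab <- tab[c(priority, setdiff(seq_len(nrow(tab)), priority)), ]
    tab <- tab[seq_len(n), ]
    tab$region_id <- seq_len(n)
    rownames(tab) <- NULL
  }
  tab
}

#' Build a synthetic block parcellation
#'
#' Tiles \code{n_regions} disjoint cubic blocks (each of at least 27
#' voxels) on a regular lattice over the grid, and assigns region names
#' and lobe groups from the fixed 96-entry vocabulary
#' ([atlasRegionTable()]). Which block hosts which region is a seeded
#' permutation, so two calls with the same seed produce identical label
#' grids.
#'
#' @param n_regions number of regions (default 96).
#' @param grid_shape integer length-3 grid dimensions
#'   (default \code{c(37, 25, 25)}, which hosts exactly 96 blocks of 5^3
#'   voxels with 1-voxel gaps).
#' @param block edge length of each cubic region block in voxels
#'   (default 5; must give >= 27 voxels per region).
#' @param gap spacing between blocks in voxels (default 1).
#' @param seed RNG seed for the block-assignment permutation.
#' @return A [Parcellation-class].
#' @export
buildAtlas <- function(n_regions = 96L, grid_shape = c(37L, 25L, 25L),
                       block = 5L, gap = 1L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  block <- as.integer(block); gap <- as.integer(gap)
  if (block^3 < 27L) stop("block edge must give regions of >= 27 voxels")
  stride <- block + gap
  ncap <- pmax((grid_shape - gap) %/% stride, 0L)
  if (prod(ncap) < n_regions)
    stop(sprintf(paste0("grid %s is too small for %d blocks of %d^3 voxels ",
                        "(capacity %d); need at least %d lattice cells"),
                 paste(grid_shape, collapse = "x"), n_regions, block,
                 prod(ncap), n_regions))
  cells <- as.matrix(expand.grid(x = seq_len(ncap[1]), y = seq_len(ncap[2]),
                                 z = seq_len(ncap[3])))
  perm <- .with_seed(seed, sample.int(nrow(cells)))
  cells <- cells[perm[seq_len(n_regions)], , drop = FALSE]
  lab <- array(0L, grid_shape)
  off <- seq_len(block) - 1L
  for (r in seq_len(n_regions)) {
    o <- gap + (cells[r, ] - 1L) * stride
    lab[o[1] + off + 1L, o[2] + off + 1L, o[3] + off + 1L] <- r
  }
  new("Parcellation", labels = lab, regions = atlasRegionTable(n_regions))
}

# Evaluate an expression under a private RNG state, restoring the
# caller's state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
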