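#' Texture classes of the 12-class FAO/USDA triangle
#'
#' @return Named character vector mapping class codes to full names.
#' @export
texture_class_names <- function() {
  c(S = "sand", LS = "loamy sand", SL = "sandy loam", L = "loam",
    SiL = "silt loam", Si = "silt", SCL = "sandy clay loam",
    CL = "clay loam", SiCL = "silty clay loam", SC = "sandy clay",
    SiC = "silty clay", C = "clay")
}

#' Classify a particle-size triplet on the FAO/USDA texture triangle
#'
#' Maps sand/silt/clay percentages of the fine earth onto the 12-class
#' triangle. Triplets whose sum deviates from 100 by up to 0.5 (percentage
#' points) are renormalized with a message; larger deviations error.
#' Class polygons are implemented as a fixed decision cascade with
#' half-open boundaries (lower bounds inclusive), so every valid triplet
#' maps to exactly one class.
#'
#' @param sand,silt,clay Percentages of fine earth; vectorized.
#' @return Character vector of class codes (`"S"`, `"LS"`, `"SL"`, `"L"`,
#'   `"SiL"`, `"Si"`, `"SCL"`, `"CL"`, `"SiCL"`, `"SC"`, `"SiC"`, `"C"`);
#'   see [texture_class_names()].
#' @examples
#' classify_texture(24, 65, 11)   # "SiL"
#' classify_texture(100, 0, 0)    # "S"
#' @export
classify_texture <- function(sand, silt, clay) {
  n <- max(length(sand), length(silt), length(clay))
  sand <- rep_len(sand, n); silt <- rep_len(silt, n); clay <- rep_len(clay, n)
  if (any(!is.finite(sand)) || any(!is.finite(silt)) || any(!is.finite(clay)) ||
      any(sand < 0) || any(silt < 0) || any(clay < 0))
    stop("sand, silt, clay must be non-negative percentages", call. = FALSE)
  tot <- sand + silt + clay
  if (any(abs(tot - 100) > 0.5))
    stop("sand + silt + clay must sum to 100 (+/- 0.5)", call. = FALSE)
  if (any(abs(tot - 100) > 1e-9)) {
    message("renormalizing texture triplet(s) whose sum deviates from 100 ",
            "within tolerance")
    sand <- 100 * sand / tot; silt <- 100 * silt / tot; clay <- 100 * clay / tot
  }
  classify_one <- function(sa, si, cl) {
    if (si + 1.5 * cl < 15) return("S")
    if (si + 2 * cl < 30) return("LS")
    if (cl >= 35 && sa > 45) return("SC")
    if (cl >= 40 && si >= 40) return("SiC")
    if (cl >= 40) return("C")
    if (cl >= 27 && sa <= 20) return("SiCL")
    if (cl >= 27 && sa <= 45) return("CL")
    if (cl >= 20 && si < 28 && sa > 45) return("SCL")
    if (si >= 80 && cl < 12) return("Si")
    if (si >= 50) return("SiL")
    if (cl >= 7 && si >= 28 && sa <= 52) return("L")
    "SL"
  }
  vapply(seq_len(n), function(i) classify_one(sand[i], silt[i], clay[i]),
         character(1L))
}
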