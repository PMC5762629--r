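## CIE 1931 2-degree standard observer color-matching functions and the D65
## illuminant relative spectral power distribution, tabulated on the same
## 380-730 nm / 10 nm grid as the reflectance tables.
cie_xyz_cmf <- matrix(c(
  0.001368, 0.000039, 0.006450,
  0.004243, 0.000120, 0.020050,
  0.014310, 0.000396, 0.067850,
  0.043510, 0.001210, 0.207400,
  0.134380, 0.004000, 0.645600,
  0.283900, 0.011600, 1.385600,
  0.348280, 0.023000, 1.747060,
  0.336200, 0.038000, 1.772110,
  0.290800, 0.060000, 1.669200,
  0.195360, 0.090980, 1.287640,
  0.095640, 0.139020, 0.812950,
  0.032010, 0.208020, 0.465180,
  0.004900, 0.323000, 0.272000,
  0.009300, 0.503000, 0.158200,
  0.063270, 0.710000, 0.078250,
  0.165500, 0.862000, 0.042160,
  0.290400, 0.954000, 0.020300,
  0.433450, 0.994950, 0.008750,
  0.594500, 0.995000, 0.003900,
  0.762100, 0.952000, 0.002100,
  0.916300, 0.870000, 0.001650,
  1.026300, 0.757000, 0.001100,
  1.062200, 0.631000, 0.000800,
  1.002600, 0.503000, 0.000340,
  0.854450, 0.381000, 0.000190,
  0.642400, 0.265000, 0.000050,
  0.447900, 0.175000, 0.000020,
  0.283500, 0.107000, 0.000000,
  0.164900, 0.061000, 0.000000,
  0.087400, 0.032000, 0.000000,
  0.046770, 0.017000, 0.000000,
  0.022700, 0.008210, 0.000000,
  0.011359, 0.004102, 0.000000,
  0.005790, 0.002091, 0.000000,
  0.002899, 0.001047, 0.000000,
  0.001440, 0.000520, 0.000000), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("x", "y", "z")))

cie_d65 <- c(49.9755, 54.6482, 82.7549, 91.4860, 93.4318, 86.6823,
             104.8650, 117.0080, 117.8120, 114.8610, 115.9230, 108.8110,
             109.3540, 107.8020, 104.7900, 107.6890, 104.4050, 104.0460,
             100.0000, 96.3342, 95.7880, 88.6856, 90.0062, 89.5991,
             87.6987, 83.2886, 83.6992, 80.0268, 80.2146, 82.2778,
             78.2842, 69.7213, 71.6091, 74.3490, 61.6040, 69.8856)

## XYZ (D65, 2 deg) -> linear sRGB
srgb_matrix <- matrix(c(
   3.2404542, -1.5371385, -0.4985314,
  -0.9692660,  1.8760108,  0.0415560,
   0.0556434, -0.2040259,  1.0572252), nrow = 3, byrow = TRUE,
  dimnames = list(c("R", "G", "B"), c("X", "Y", "Z")))

srgb_compand <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Convert a reflectance spectrum to a 0-1 brightness value
#'
#' Implements the standard colorimetric chain used to score plumage
#' brightness: reflectance x D65 illuminant integrated against the CIE 1931
#' 2-degree observer (normalised so a perfect reflector has Y = 1), the
#' standard XYZ-to-linear-sRGB matrix, sRGB gamma companding, clipping to
#' \[0, 1\]. The green channel is returned: 0 = black (dark), 1 = white
#' (bright).
#'
#' @param spectrum numeric vector of 36 reflectance fractions on the
#'   380-730 nm / 10 nm grid, or a [spectrum_table()] (one value per row).
#' @return Brightness in \[0, 1\] (vector for a table).
#' @export
spectrum_to_brightness <- function(spectrum) {
  if (is.matrix(spectrum)) {
    return(vapply(seq_len(nrow(spectrum)), function(i) {
      spectrum_to_brightness(as.numeric(spectrum[i, ]))
    }, 0))
  }
  wl <- spectrum_wavelengths()
  if (length(spectrum) != length(wl)) {
    stop(sprintf("expected reflectance on the %d-point 380-730 nm grid",
                 length(wl)))
  }
  norm <- sum(cie_d65 * cie_xyz_cmf[, "y"])
  xyz <- colSums(cie_d65 * spectrum * cie_xyz_cmf) / norm
  rgb_lin <- as.numeric(srgb_matrix %*% xyz)
  rgb <- pmin(pmax(srgb_compand(pmin(pmax(rgb_lin, 0), 1)), 0), 1)
  rgb[2]
}

#' Score a spectrum table into a brightness phenotype table
#'
#' @param spectra a [spectrum_table()].
#' @param trait trait name (should contain "brightness" so the phenotype
#'   validator applies the 0-1 bound).
#' @param meta optional data.frame with columns `individual, population,
#'   region, sex, year` aligned with the rows of `spectra`; defaults are
#'   filled in when absent.
#' @return A `phenotype_table` of brightness values.
#' @export
brightness_phenotypes <- function(spectra, trait = "brightness", meta = NULL) {
  b <- spectrum_to_brightness(spectra)
  n <- length(b)
  if (is.null(meta)) {
    meta <- data.frame(individual = rownames(spectra) %||% paste0("s", 1:n),
                       population = "P01", region = "R1", sex = "M",
                       year = 2015, stringsAsFactors = FALSE)
  }
  validate_phenotypes(data.frame(meta, trait = trait, value = b,
                                 stringsAsFactors = FALSE))
}
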