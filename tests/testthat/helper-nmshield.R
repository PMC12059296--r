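# shared helpers for the test suite

# independent transcription of the published Archer parameter table used by
# the transcription tests (nuclide, material, alpha, beta, gamma)
published_archer <- function() {
  read.csv(text = "nuclide,material,alpha,beta,gamma
Tc-99m,lead,2.558,1.010,4.344
Tc-99m,gypsum,0.009549,-0.005312,1.430
Tc-99m,LW concrete,0.02047,-0.01122,0.4389
Tc-99m,NW concrete,0.03102,-0.01729,0.3622
Tc-99m,A514 steel,0.1581,-0.04346,0.2602
Tc-99m,glass,0.03419,-0.02009,0.3076
Lu-177,lead,0.3855,1.071,0.2822
Lu-177,gypsum,0.009594,-0.003783,0.3739
Lu-177,LW concrete,0.01615,-0.007056,0.5194
Lu-177,NW concrete,0.02477,-0.01173,0.4404
Lu-177,A514 steel,0.0797,2.243,28.74
Lu-177,glass,0.02456,-0.01197,0.6480
I-131,lead,0.1082,0.2072,0.5385
I-131,LW concrete,0.01363,-0.007896,0.4847
I-131,NW concrete,0.02062,-0.01220,0.4179
I-131,A514 steel,0.05786,-0.02574,0.8742
I-131,glass,0.02191,-0.01319,0.4497
F-18,lead,0.166,-0.02184,0.2436
F-18,LW concrete,0.01126,-0.006463,0.7475
F-18,NW concrete,0.01558,-0.008775,0.8600
F-18,A514 steel,0.05032,-0.02632,1.223",
    stringsAsFactors = FALSE)
}

# independent transcription of the published fractional value layers (mm),
# same row order as published_archer(); columns HVL/QVL/TVL/CVL/MVL
published_value_layers <- function() {
  vals <- matrix(c(
    0.243, 0.512, 0.870, 1.77, 2.67,
    115, 199, 299, 542, 783,
    64.6, 117, 176, 305, 423,
    44.3, 80.6, 122, 211, 291,
    5.86, 11.4, 18.4, 34.8, 50.4,
    43.3, 78.8, 119, 204, 279,
    0.511, 1.10, 1.99, 4.91, 8.76,
    111, 210, 329, 599, 851,
    68.0, 126, 194, 349, 495,
    47.5, 87.5, 134, 239, 336,
    7.23, 15.9, 27.4, 56.3, 85.2,
    46.8, 84.5, 128, 228, 323,
    2.48, 5.54, 10.5, 26.8, 46.3,
    101, 180, 268, 459, 635,
    69.7, 124, 186, 317, 435,
    18.1, 32.8, 50.2, 91.1, 131,
    66.2, 117, 174, 296, 406,
    4.75, 9.40, 15.4, 30.1, 44.5,
    113, 197, 293, 508, 714,
    78.6, 137, 204, 357, 505,
    21.7, 37.9, 57.3, 104, 149), ncol = 5, byrow = TRUE)
  colnames(vals) <- c("HVL", "QVL", "TVL", "CVL", "MVL")
  vals
}

# one unit in the last printed digit of a 3-significant-figure value
ulp3 <- function(x) 10^(floor(log10(abs(x))) - 2)

expect_signif3 <- function(computed, printed) {
  expect_equal(signif(computed, 3), printed, tolerance = 1e-12)
}
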