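# Builds inst/extdata/hemoglobin_synthetic.tsv: a synthetic whole-blood
# absorption table standing in for the public oxy/deoxy-haemoglobin
# compilations.  Molar extinction anchors (M^-1 cm^-1) are
# literature-typical values for the main spectral features (Soret band,
# the oxyhaemoglobin 542/578 nm "W" doublet, the deoxy 555 nm band and
# 760 nm shoulder); between anchors the curve is a natural cubic spline
# in log-extinction.  Conversion to whole-blood absorption uses
# 150 g/L haemoglobin, molar mass 64500 g/mol and the ln(10) factor:
#   mu_a = ln(10) * eps * 150 / 64500   [cm^-1]
# Regenerate with: Rscript tools/make_hemoglobin_table.R

oxy_anchors <- data.frame(
  wl  = c(400, 406, 414, 422, 430, 440, 450, 470, 490, 510, 530, 542,
          550, 560, 570, 578, 586, 600, 620, 650, 700, 750, 800, 850,
          900, 950, 1000),
  eps = c(266000, 350000, 480000, 300000, 110000, 55000, 36000, 24000,
          20500, 22500, 40000, 53200, 45000, 32600, 42000, 53500, 30000,
          3200, 1100, 368, 290, 562, 816, 1058, 1198, 1204, 1103)
)

deoxy_anchors <- data.frame(
  wl  = c(400, 410, 420, 430, 440, 450, 470, 490, 510, 530, 545, 555,
          565, 576, 590, 600, 620, 650, 680, 700, 730, 760, 780, 800,
          850, 900, 950, 1000),
  eps = c(223000, 290000, 410000, 533000, 240000, 103000, 40000, 23000,
          21000, 32000, 48000, 53400, 50500, 42000, 25000, 14700, 7500,
          3750, 2250, 1795, 1100, 1670, 1130, 761, 690, 730, 690, 650)
)

wl_out <- seq(400, 1000, by = 2)
spl <- function(a) exp(spline(a$wl, log(a$eps), xout = wl_out,
                              method = "natural")$y)
to_mua <- function(eps) log(10) * eps * 150 / 64500

tab <- data.frame(
  wavelength_nm  = wl_out,
  mu_a_oxy_cm1   = round(to_mua(spl(oxy_anchors)), 5),
  mu_a_deoxy_cm1 = round(to_mua(spl(deoxy_anchors)), 5)
)
stopifnot(all(tab$mu_a_oxy_cm1 > 0), all(tab$mu_a_deoxy_cm1 > 0))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "inst/extdata/hemoglobin_synthetic.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(tab), "rows\n")
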