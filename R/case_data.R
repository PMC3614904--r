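# Frozen geometry of the case-study scaffold: a 33-residue helix-hairpin
# mini-protein whose sequence was made self-consistent with the package's
# design procedure (iterated fixed-backbone design on the relaxed fold),
# so that core positions are genuinely preferred by the energy model.
# Torsions are stored to full precision; the structure is rebuilt from
# ideal-geometry templates at run time.
.case_seq <- "SETIAIEAASKTKQTKLAANKQEKSSEAEDKTA"
.case_phi <- c(-57.000000, -50.538653, -40.789966, -101.990378, -74.786674, -49.740736, 49.749891, -11.214418, -43.717666, -58.833476, -57.066985, -53.967140, -108.421850, -36.580210, -47.737422, -70.777227, 49.478211, -72.538389, 48.941366, -55.405347, -87.686526, -48.818798, -62.529985, -53.128547, -73.973302, -50.855812, -52.676009, -52.122532, -133.632978, -114.235847, -50.978576, -49.944166, -73.924416)
.case_psi <- c(179.686055, -38.535513, -52.320305, -16.169933, -3.667660, -37.086882, -105.617307, -65.270355, -89.024982, -29.355249, -61.713307, -25.722245, -96.524995, -63.341174, -65.064061, 15.430876, 62.393902, 25.340616, -111.868676, -34.652932, -14.223029, -73.840178, -20.204558, -87.455637, 2.271341, -22.380344, -31.632540, -17.141089, -17.397105, -86.528013, -77.484372, -21.974458, -47.000000)
.case_chi <- list(
  c(62.155729),
  c(174.595148, 52.256774, 59.823175),
  c(62.230057),
  c(-179.793005, 178.288491),
  numeric(0),
  c(-58.446981, -175.232278),
  c(-52.347304, -51.544860, -60.188582),
  numeric(0),
  numeric(0),
  c(59.340354),
  c(-175.794678, -179.890630, -60.986427, -58.304210),
  c(60.259282),
  c(-61.780541, -57.141339, -178.584342, 61.542960),
  c(-179.727107, 59.597019, -124.271142),
  c(-61.487305),
  c(-52.860608, -178.669235, -177.969722, 63.431450),
  c(-56.844088, -176.554849),
  numeric(0),
  numeric(0),
  c(64.065929, 121.906699),
  c(-56.601782, 176.579253, -55.288571, -56.434688),
  c(-170.494485, 174.021598, 120.654446),
  c(177.888652, 52.560588, 60.011102),
  c(170.928761, -177.385252, 52.516119, 57.304518),
  c(-179.436357),
  c(172.941893),
  c(58.578004, -179.656351, 179.471648),
  numeric(0),
  c(54.124292, -172.987120, -59.249409),
  c(-59.670926, -178.616267),
  c(-60.677107, 178.895708, -66.177383, -59.142212),
  c(-60.809609),
  numeric(0)
)
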