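#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Specular reflectivity of a stratified medium by the Abelès
// characteristic-matrix method with Névot-Croce roughness damping.
//
// Layers run from 0 (fronting, semi-infinite) to nl-1 (backing,
// semi-infinite).  rough[j] is the roughness of the interface between
// layers j and j+1 (length nl-1).  sld_im >= 0 means absorption; the
// kernel works in the e^{-i omega t} convention, so internally
//   kz_j^2 = kz0^2 - 4*pi*(d_re - i*d_im),  d = rho_j - rho_0,
// whose principal square root has Re >= 0 and Im >= 0 for passive
// media (decaying transmitted/evanescent waves).
// [[Rcpp::export(name = ".abeles_kernel")]]
NumericVector abeles_kernel(NumericVector Q,
                            NumericVector sld_re,
                            NumericVector sld_im,
                            NumericVector thickness,
                            NumericVector rough) {
  const int nq = Q.size();
  const int nl = sld_re.size();
  if (nl < 2) stop("at least 2 layers (fronting and backing) are required");
  if (sld_im.size() != nl || thickness.size() != nl)
    stop("sld_re, sld_im and thickness must have equal length");
  if (rough.size() != nl - 1)
    stop("rough must have length (number of layers - 1)");

  const double FOURPI = 4.0 * M_PI;
  NumericVector out(nq);
  std::vector<cplx> kz(nl);

  for (int iq = 0; iq < nq; ++iq) {
    const double q = Q[iq];
    if (!(q > 0.0)) stop("Q must be strictly positive");
    const double k0 = 0.5 * q;

    for (int j = 0; j < nl; ++j) {
      const double dre = sld_re[j] - sld_re[0];
      const double dim = sld_im[j] - sld_im[0];
      cplx arg(k0 * k0 - FOURPI * dre, FOURPI * dim);
      cplx k = std::sqrt(arg);
      if (k.imag() < 0.0) k = -k;  // decaying branch for -0 imaginary parts
      kz[j] = k;
    }

    // accumulate M = prod_j [ e^{-i b_j}, r_j e^{-i b_j} ; r_j e^{i b_j}, e^{i b_j} ]
    // with b_0 = 0 and b_j = kz_j * d_j for interior layers.
    cplx M11(1.0, 0.0), M12(0.0, 0.0), M21(0.0, 0.0), M22(1.0, 0.0);
    for (int j = 0; j < nl - 1; ++j) {
      const cplx kj = kz[j], kn = kz[j + 1];
      cplx r = (kj - kn) / (kj + kn);
      const double sig = rough[j];
      if (sig > 0.0)
        r *= std::exp(-2.0 * kj * kn * sig * sig);
      cplx ep(1.0, 0.0), em(1.0, 0.0);
      if (j > 0) {
        const cplx ib = cplx(0.0, 1.0) * kj * thickness[j];
        ep = std::exp(ib);
        em = std::exp(-ib);
      }
      const cplx A11 = em, A12 = r * em, A21 = r * ep, A22 = ep;
      const cplx N11 = M11 * A11 + M12 * A21;
      const cplx N12 = M11 * A12 + M12 * A22;
      const cplx N21 = M21 * A11 + M22 * A21;
      const cplx N22 = M21 * A12 + M22 * A22;
      M11 = N11; M12 = N12; M21 = N21; M22 = N22;
    }
    const cplx rtot = M21 / M11;
    double R = std::norm(rtot);
    if (R < 0.0) R = 0.0;
    out[iq] = R;
  }
  return out;
}
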