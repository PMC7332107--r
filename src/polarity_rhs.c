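/* Right-hand side of the six-pool MglA/MglB/RomR polarity ODE model.
 *
 * State vector y = (A1, A2, B1, B2, R1, R2): fractions of total MglA, MglB
 * and RomR/RomX at poles 1 and 2.  Cytoplasmic pools are X_c = 1 - X1 - X2.
 *
 * Parameter vector (see R/model_core.R, .model_parms_vector):
 *   0 aA   basal MglA polar binding rate          (1/min)
 *   1 aB   basal MglB polar binding rate          (1/min)
 *   2 aR   basal RomR polar binding rate          (1/min)
 *   3 bR   RomR self-recruitment coefficient      (1/min)
 *   4 cA   RomR/RomX -> MglA recruitment          (1/min)
 *   5 cB   RomR -> MglB recruitment               (1/min)
 *   6 cR   MglB -> RomR recruitment               (1/min)
 *   7 dA   basal MglA dissociation                (1/min)
 *   8 dB   basal MglB dissociation                (1/min)
 *   9 dR1  RomR dissociation at pole 1 (old-pole bias folded in) (1/min)
 *  10 dR2  RomR dissociation at pole 2            (1/min)
 *  11 dAB  MglB-driven MglA dissociation strength (1/min)
 *  12 dBA  MglA-driven MglB dissociation strength (1/min)
 *  13 K    MglA suppression constant for MglB->RomR recruitment (fraction)
 *  14-16   presence flags for MglA, MglB, RomR (0 = deleted)
 *
 * K >= 1e30 is treated as the K -> infinity limit (suppression off).
 */

static double parms[17];

void mxpol_initmod(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, parms);
}

void mxpol_rhs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double aA = parms[0], aB = parms[1], aR = parms[2], bR = parms[3];
    const double cA = parms[4], cB = parms[5], cR = parms[6];
    const double dA = parms[7], dB = parms[8];
    const double dR1 = parms[9], dR2 = parms[10];
    const double dAB = parms[11], dBA = parms[12], K = parms[13];
    const double pA = parms[14], pB = parms[15], pR = parms[16];

    const double A1 = y[0], A2 = y[1], B1 = y[2], B2 = y[3];
    const double R1 = y[4], R2 = y[5];

    const double Ac = 1.0 - A1 - A2;
    const double Bc = 1.0 - B1 - B2;
    const double Rc = 1.0 - R1 - R2;

    /* K/(K + A): MglA suppression of MglB->RomR recruitment */
    const double s1 = (K >= 1e30) ? 1.0 : K / (K + A1);
    const double s2 = (K >= 1e30) ? 1.0 : K / (K + A2);

    ydot[0] = pA * (Ac * (aA + cA * R1) - dA * A1 - dAB * A1 * B1 * B1);
    ydot[1] = pA * (Ac * (aA + cA * R2) - dA * A2 - dAB * A2 * B2 * B2);
    ydot[2] = pB * (Bc * (aB + cB * R1) - dB * B1 - dBA * A1 * B1 * B1);
    ydot[3] = pB * (Bc * (aB + cB * R2) - dB * B2 - dBA * A2 * B2 * B2);
    ydot[4] = pR * (Rc * (aR + bR * R1 + cR * B1 * s1) - dR1 * R1);
    ydot[5] = pR * (Rc * (aR + bR * R2 + cR * B2 * s2) - dR2 * R2);
}
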