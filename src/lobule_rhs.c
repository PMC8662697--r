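/* Compiled right-hand side of the coupled lobule/body system.
 *
 * State layout (0-based blocks of N): r, IP3, CaI, g, Glyc, Gcell,
 * Glc, Ins, Glu, Epn, NEpn, then 5 body states (GB, Ins_B, Glu_B,
 * Epn_B, NEpn_B). Parameters arrive as a flat vector: 51 scalars
 * followed by the per-cell vectors k_r, k_IP3, w, mask, padded to a
 * fixed length (layout mirrored in pack_params() on the R side).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXCELLS 64
#define NPARMS (52 + 4 * MAXCELLS)

static double parms[NPARMS];

void hepacal_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double pow4frac(double x, double k)
{
    /* x^4 / (k + x)^4 */
    double q = x / (k + x);
    q *= q;
    return q * q;
}

void hepacal_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = parms;
    const int N = (int) p[0];
    const double A = p[1], B = p[2], D = p[3], E = p[4], F = p[5];
    const double k1 = p[6], k2 = p[7], k3 = p[8], k_cat = p[9];
    const double k_d = p[10], k_Hr = p[11], L = p[12], CaT = p[13];
    const double Gij = p[14];
    const double CaI_GPK = p[15], K_gpk = p[16], v0 = p[17];
    const double v_brk = p[18], Km_Glyc = p[19], Km_Phos = p[20];
    const double n_brk = p[21], v_CaI_max = p[22];
    const double k_LP = p[23], k_IP = p[24], Phos = p[25];
    const double k_export = p[26], bf = p[27], s = p[28];
    const double k_cl_i = p[29], k_cl_g = p[30], k_cl_c = p[31];
    const double G_ref = p[32], tau_glu = p[33], km_glu = p[34];
    const double n_glu = p[35], tau_ins = p[36], km_ins = p[37];
    const double n_ins = p[38], Km_symp = p[39], G_symp = p[40];
    const double G_au_scale = p[41];
    const double v_Epn = p[42], v_NEpn = p[43];
    const double X_Epn = p[44], X_NEpn = p[45], K_stim = p[46];
    const double u_G = p[47], variant_alt = p[48];
    const double v_glu_alt = p[49], km_glu_alt = p[50];
    const double stim_on = p[51];
    const double *k_r = p + 52;
    const double *k_ip3 = p + 52 + MAXCELLS;
    const double *w = p + 52 + 2 * MAXCELLS;
    const double *mask = p + 52 + 3 * MAXCELLS;

    const double *r = y, *IP3 = y + N, *CaI = y + 2 * N, *g = y + 3 * N;
    const double *Glyc = y + 4 * N, *Gcell = y + 5 * N;
    const double *Glc = y + 6 * N, *Ins = y + 7 * N, *Glu = y + 8 * N;
    const double *Epn = y + 9 * N, *NEpn = y + 10 * N;
    const double GB = y[11 * N] > 1e-9 ? y[11 * N] : 1e-9;
    const double InsB = y[11 * N + 1], GluB = y[11 * N + 2];
    const double EpnB = y[11 * N + 3], NEpnB = y[11 * N + 4];

    double cns = 0.0;
    if (GB < G_symp) {
        double dev = G_symp - GB;
        cns = dev / (Km_symp + dev);
    }

    const double KmG_n = pow(Km_Glyc, n_brk);
    const double phos_fac = Phos / (Km_Phos + Phos);

    for (int i = 0; i < N; i++) {
        double ri = r[i];
        if (ri < 0) ri = 0; else if (ri > 1) ri = 1;
        double ip = IP3[i] > 0 ? IP3[i] : 0;
        double ca = CaI[i] > 0 ? CaI[i] : 0;
        double gi = g[i];
        if (gi < 0) gi = 0; else if (gi > 1) gi = 1;
        double gly = Glyc[i] > 0 ? Glyc[i] : 0;
        double ins = Ins[i] > 0 ? Ins[i] : 0;
        double glu = Glu[i] > 0 ? Glu[i] : 0;
        double epn = Epn[i] > 0 ? Epn[i] : 0;
        double nepn = NEpn[i] > 0 ? NEpn[i] : 0;

        double H = stim_on * (epn + nepn + K_stim * cns * mask[i]);

        /* receptor */
        ydot[i] = k_r[i] * (1 - ri) - k_d * ri - k_Hr * H * ri;

        /* IP3 with no-flux chain ends */
        double up = (i > 0) ? (IP3[i - 1] > 0 ? IP3[i - 1] : 0) : ip;
        double dn = (i < N - 1) ? (IP3[i + 1] > 0 ? IP3[i + 1] : 0) : ip;
        double couple = Gij * ((up - ip) + (dn - ip));
        ydot[N + i] = k_ip3[i] * H * ri / (k_cat + ri) * ca / (ca + k3)
            - D * ip + couple;

        /* cytosolic calcium */
        ydot[2 * N + i] = (1 - gi) * (A * pow4frac(ip, k1) + L) * (CaT - ca)
            - B * ca * ca / (k2 * k2 + ca * ca);

        /* IP3R fraction, clamped at the bounds */
        double ca2 = ca * ca;
        double dg = E * ca2 * ca2 * (1 - gi) - F;
        if ((g[i] <= 0 && dg < 0) || (g[i] >= 1 && dg > 0)) dg = 0;
        ydot[3 * N + i] = dg;

        /* glycogenolysis and glucose export */
        double act = (ca > CaI_GPK) ? ca / (K_gpk + ca) : v0;
        double kp = (glu * 1000.0 + k_LP) / (ins * 1000.0 + k_IP);
        double gn = pow(gly, n_brk);
        double flux = w[i] * v_brk * kp * gn / (gn + KmG_n) * phos_fac
            * (1 + v_CaI_max * act);
        double export = k_export * (Gcell[i] - Glc[i]);
        ydot[4 * N + i] = -flux / 1000.0;
        ydot[5 * N + i] = flux - export;

        /* advection + local source/sink for the five blood species */
        double glc_up = (i > 0) ? Glc[i - 1] : GB;
        double ins_up = (i > 0) ? Ins[i - 1] : InsB;
        double glu_up = (i > 0) ? Glu[i - 1] : GluB;
        double epn_up = (i > 0) ? Epn[i - 1] : EpnB;
        double nepn_up = (i > 0) ? NEpn[i - 1] : NEpnB;
        ydot[6 * N + i] = bf * (glc_up - Glc[i]) + export;
        ydot[7 * N + i] = bf * (ins_up - Ins[i]) - k_cl_i * ins;
        ydot[8 * N + i] = bf * (glu_up - Glu[i]) - k_cl_g * glu;
        ydot[9 * N + i] = bf * (epn_up - Epn[i]) - k_cl_c * epn;
        ydot[10 * N + i] = bf * (nepn_up - NEpn[i]) - k_cl_c * nepn;
    }

    /* pancreatic secretion on the a.u. glucose scale */
    double GB_au = GB / G_au_scale;
    double x = log(G_ref / GB_au);
    double sec_glu = 0.0, sec_ins = 0.0;
    if (GB_au < G_ref) {
        double xn = pow(x, n_glu);
        sec_glu = (1.0 / tau_glu) * xn / (pow(km_glu, n_glu) + xn);
        if (variant_alt > 0)
            sec_glu += v_glu_alt * cns / (km_glu_alt + cns);
    } else if (GB_au > G_ref) {
        double yn = pow(-x, n_ins);
        sec_ins = (1.0 / tau_ins) * yn / (pow(km_ins, n_ins) + yn);
    }
    double sec_epn, sec_nepn;
    if (variant_alt > 0) {
        sec_epn = v_Epn;
        sec_nepn = v_NEpn;
    } else {
        sec_epn = v_Epn * (1 + X_Epn * cns);
        sec_nepn = v_NEpn * (1 + X_NEpn * cns);
    }

    ydot[11 * N] = bf * (Glc[N - 1] - y[11 * N]) / s - u_G;
    ydot[11 * N + 1] = bf * (Ins[N - 1] - InsB) / s + sec_ins / s;
    ydot[11 * N + 2] = bf * (Glu[N - 1] - GluB) / s + sec_glu / s;
    ydot[11 * N + 3] = bf * (Epn[N - 1] - EpnB) / s + sec_epn / s;
    ydot[11 * N + 4] = bf * (NEpn[N - 1] - NEpnB) / s + sec_nepn / s;
}

static const R_CMethodDef cMethods[] = {
    {"hepacal_derivs", (DL_FUNC) &hepacal_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_hepacal(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
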